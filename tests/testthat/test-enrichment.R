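test_that("variant_frequency is the exact ratio and rejects zero totals", {
  expect_equal(variant_frequency(0, 100), 0)
  expect_equal(variant_frequency(250, 1000), 0.25)
  expect_error(variant_frequency(5, 0), "zero")
  expect_error(variant_frequency(11, 10), "0 <=")
})

test_that("fold_change follows the frequency-ratio definition", {
  expect_equal(fold_change(2000, 1e5, 10, 1e5), 200)  # 0.02 / 0.0001
  expect_equal(fold_change(37, 500, 74, 1000), 1)      # equal frequencies
  # zero-library variant: finite under pseudocount, matches hand arithmetic
  fc <- fold_change(120, 1e5, 0, 1e5, policy = "pseudocount", pseudo = 0.5)
  expect_equal(fc, (120.5 / 1e5) / (0.5 / 1e5))
  expect_true(is.na(fold_change(120, 1e5, 0, 1e5, policy = "strict")))
  expect_error(fold_change(1, 0, 1, 10), "zero")
})

test_that("exact test matches the hypergeometric oracle", {
  expect_equal(enrichment_test(10, 1e4, 10, 1e4), 1.0)
  p <- enrichment_test(10, 1e4, 500, 1e4)
  expect_equal(p, oracle_fisher_p(10, 1e4, 500, 1e4), tolerance = 1e-10)

  set.seed(7)
  for (i in 1:200) {
    n1 <- sample(2:100, 1); n2 <- sample(2:100, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(enrichment_test(a, n1, b, n2),
                 oracle_fisher_p(a, n1, b, n2), tolerance = 1e-10)
  }
})

test_that("normal approximation tracks the exact test at large cells", {
  set.seed(8)
  for (i in 1:40) {
    n1 <- sample(5000:20000, 1); n2 <- sample(5000:20000, 1)
    a <- sample(50:300, 1); b <- sample(50:300, 1)
    pe <- enrichment_test(a, n1, b, n2, method = "exact")
    pa <- enrichment_test(a, n1, b, n2, method = "approx")
    if (pe > 1e-8) {  # compare away from the extreme tail
      expect_lt(abs(log(pa) - log(pe)), log(1.5))
    }
  }
})

test_that("BH adjustment matches hand computation and is order-invariant", {
  expect_equal(adjust_bh(0.037), 0.037)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- adjust_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(adjust_bh(p[perm]), q[perm])
  }
})

make_screen_tables <- function(n_variants, n_hits, depth = 1e5,
                               lib_reads = 100L, hit_fold = 60) {
  cds <- random_cds(ceiling(n_variants / 3) + 2, seed = 1234)
  sp <- enumerate_snv_space(cds)
  nt <- sp$nt_variants[seq_len(n_variants), ]
  tp_reads <- rep(lib_reads, n_variants)
  tp_reads[seq_len(n_hits)] <- lib_reads * hit_fold
  list(space = sp,
       lib = make_counts(nt$pos, nt$ref, nt$alt, rep(lib_reads, n_variants),
                         rep(depth, n_variants), id = "lib"),
       tp = make_counts(nt$pos, nt$ref, nt$alt, as.integer(tp_reads),
                        rep(depth, n_variants), id = "tp"))
}

test_that("score_screen partitions hits and passengers at the thresholds", {
  s <- make_screen_tables(200, 4)
  res <- score_screen(s$lib, s$tp, s$space)
  expect_equal(nrow(res), 200L)
  expect_equal(sum(res$hit), 4L)
  expect_equal(sum(!res$hit), 196L)
  expect_true(all(res$fold_change[res$hit] >= 50))
  expect_true(all(res$q[res$hit] < 1e-5))
  expect_equal(attr(res, "assessable_n"), 200L)
})

test_that("score_screen is invariant to the row order of its inputs", {
  s <- make_screen_tables(120, 3)
  res1 <- score_screen(s$lib, s$tp, s$space)
  perm <- sample(nrow(s$lib))
  lib2 <- variant_count_table(as.data.frame(s$lib)[perm, ], "lib")
  tp2 <- variant_count_table(as.data.frame(s$tp)[rev(perm), ], "tp")
  res2 <- score_screen(lib2, tp2, s$space)
  expect_identical(as.data.frame(res1), as.data.frame(res2))
})

test_that("assessability excludes variants missing from either sample", {
  s <- make_screen_tables(50, 2)
  lib_df <- as.data.frame(s$lib)
  tp_df <- as.data.frame(s$tp)
  lib_df$variant_reads[10] <- 0L   # below floor in library
  tp_df$variant_reads[20] <- 0L    # absent from timepoint
  res <- score_screen(variant_count_table(lib_df, "lib"),
                      variant_count_table(tp_df, "tp"), s$space)
  expect_equal(nrow(res), 48L)
})

test_that("disjoint variant sets give an empty result with a warning", {
  s <- make_screen_tables(30, 0)
  lib_df <- as.data.frame(s$lib)[1:10, ]
  tp_df <- as.data.frame(s$tp)[21:30, ]
  expect_warning(
    res <- score_screen(variant_count_table(lib_df, "lib"),
                        variant_count_table(tp_df, "tp"), s$space),
    "no assessable")
  expect_equal(nrow(res), 0L)
})

test_that("stricter thresholds call monotonically fewer hits", {
  s <- make_screen_tables(150, 5, hit_fold = 55)
  n_default <- sum(score_screen(s$lib, s$tp, s$space)$hit)
  n_strict <- sum(score_screen(s$lib, s$tp, s$space,
                               hit_call_params(min_fold_change = 100))$hit)
  expect_lte(n_strict, n_default)
})

test_that("compare_screens intersects top lists by amino-acid identity", {
  s <- make_screen_tables(100, 6)
  res <- score_screen(s$lib, s$tp, s$space)
  self <- compare_screens(res, res, top_n = 5)
  expect_equal(self$overlap, 5L)
  expect_equal(self$shared$rank_a, self$shared$rank_b)

  # disjoint: enrich a different block of variants in screen b
  tp_df <- as.data.frame(s$tp)
  tp_df$variant_reads <- 100L
  tp_df$variant_reads[51:56] <- 6000L
  res_b <- score_screen(s$lib, variant_count_table(tp_df, "b"), s$space)
  cmp <- compare_screens(res, res_b, top_n = 5)
  expect_equal(cmp$overlap, 0L)

  expect_warning(compare_screens(res, res, top_n = 1e6), "capped")
})

test_that("screen_report assembles scatter, coverage and spectrum", {
  s <- make_screen_tables(90, 3)
  res <- score_screen(s$lib, s$tp, s$space)
  rep <- screen_report(res, s$space)
  expect_equal(nrow(rep$scatter), 90L)
  expect_equal(rep$n_hits, 3L)
  expect_true(all(rep$scatter$fold_change[rep$scatter$hit] >= 50))
  expect_equal(rep$spectrum$total, 90L)

  empty <- res[0, ]
  attr(empty, "coverage") <- attr(res, "coverage")
  rep0 <- screen_report(empty, s$space)
  expect_equal(nrow(rep0$scatter), 0L)
})

test_that("neutral simulations stay centered at fold 1 with no hits", {
  cds <- random_cds(150, seed = 61)
  n_zero_hits <- 0L
  reps <- 8L
  for (i in seq_len(reps)) {
    sim <- simulate_screen(cds, n_inserts = 4000, n_hits = 0,
                           seqmodel = sequencing_model(depth = 2e4),
                           seed = 600 + i)
    res <- score_screen(sim$counts$library, sim$counts$day8, sim$space,
                        hit_call_params(min_library_reads = 3))
    if (sum(res$hit) == 0L) n_zero_hits <- n_zero_hits + 1L
    expect_lt(abs(median(res$fold_change) - 1), 0.2)
  }
  expect_equal(n_zero_hits, reps)
})

test_that("planted fitness rank order is preserved in fold change", {
  cds <- random_cds(200, seed = 62)
  sp <- enumerate_snv_space(cds)
  lib <- simulate_library(cds, mutagenesis_model(2.59), 8000, seed = 63)
  nt <- sp$nt_variants
  idx <- match(paste(lib$mutations$pos, lib$mutations$alt),
               paste(nt$pos, nt$alt))
  present <- unique(data.frame(codon_index = nt$codon_index[idx],
                               alt_aa = nt$alt_aa[idx],
                               effect = nt$effect[idx]))
  cand <- present[present$effect == "missense", ][1:8, ]
  deltas <- seq(0.15, 0.6, length.out = 8)
  fit <- fitness_model(effects = data.frame(codon_index = cand$codon_index,
                                            alt_aa = cand$alt_aa,
                                            delta_r = deltas))
  rates <- clone_growth_rates(lib, sp, fit)
  traj <- simulate_selection(rates, passage_schedule())
  set.seed(64)
  tbl_lib <- simulate_counts(rep(1, lib$n_inserts), lib, cds,
                             sequencing_model(depth = 5e4), "lib")
  tbl_tp <- simulate_counts(traj$abundance[, 1], lib, cds,
                            sequencing_model(depth = 5e4), "tp")
  res <- score_screen(tbl_lib, tbl_tp, sp, hit_call_params(min_library_reads = 3))
  key <- paste(res$codon_index, alt_aa_of(res$aa_change))
  fold_by_aa <- tapply(res$fold_change, key, max)
  got <- fold_by_aa[paste(cand$codon_index, cand$alt_aa)]
  keep <- !is.na(got)
  expect_gte(sum(keep), 6)  # nearly all planted variants observed
  expect_gte(cor(deltas[keep], got[keep], method = "spearman"), 0.9)
})
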