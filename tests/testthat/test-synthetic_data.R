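test_that("mutagenesis model validates and normalizes its spectrum", {
  m <- mutagenesis_model(2.59)
  expect_equal(sum(m$spectrum_weights), 1)
  expect_error(mutagenesis_model(-1), ">= 0")
  expect_error(mutagenesis_model(1, c(a = 1)), "named")
})

test_that("simulate_library draws Poisson loads with uniform positions", {
  cds <- random_cds(100, seed = 2)
  lib0 <- simulate_library(cds, mutagenesis_model(0), 50, seed = 1)
  expect_equal(nrow(lib0$mutations), 0L)

  lib <- simulate_library(cds, mutagenesis_model(2.59), 5000, seed = 10)
  mean_obs <- nrow(lib$mutations) / lib$n_inserts
  se <- sqrt(2.59 / 5000)
  expect_lt(abs(mean_obs - 2.59), 3 * se)
  # in-cis constraint: one variant per position per insert
  expect_false(any(duplicated(lib$mutations[, c("insert_id", "pos")])))
  # reference bases match the CDS
  bases <- strsplit(cds$sequence, "")[[1]]
  expect_identical(lib$mutations$ref, bases[lib$mutations$pos])
  expect_false(any(lib$mutations$ref == lib$mutations$alt))
})

test_that("spectrum weights steer the drawn alternates", {
  cds <- random_cds(100, seed = 2)
  w <- stats::setNames(rep(0, 12),
                       names(mutagenesis_model()$spectrum_weights))
  w[c("A>G", "G>A", "C>T", "T>C")] <- 1  # transitions only
  lib <- simulate_library(cds, mutagenesis_model(3, w), 500, seed = 3)
  expect_true(all(classify_substitution(lib$mutations$ref,
                                        lib$mutations$alt) == "transition"))
})

test_that("fraction of inserts with a coding change obeys Poisson thinning", {
  cds <- random_cds(50, seed = 8)
  sp <- enumerate_snv_space(cds)
  rate <- 2.59
  lib <- simulate_library(cds, mutagenesis_model(rate), 20000, seed = 9)
  nt <- sp$nt_variants
  idx <- match(paste(lib$mutations$pos, lib$mutations$alt),
               paste(nt$pos, nt$alt))
  coding_ids <- unique(lib$mutations$insert_id[
    nt$effect[idx] %in% c("missense", "nonsense")])
  frac <- length(coding_ids) / lib$n_inserts
  lambda_aa <- rate * sp$counts$nt_missense_nonsense / sp$counts$nt_total
  want <- 1 - exp(-lambda_aa)
  se <- sqrt(want * (1 - want) / lib$n_inserts)
  expect_lt(abs(frac - want), 4 * se)
})

test_that("identical seeds give bit-identical simulations", {
  cds <- random_cds(60, seed = 4)
  a <- simulate_screen(cds, n_inserts = 500, n_hits = 2,
                       seqmodel = sequencing_model(depth = 5000), seed = 99)
  b <- simulate_screen(cds, n_inserts = 500, n_hits = 2,
                       seqmodel = sequencing_model(depth = 5000), seed = 99)
  expect_identical(a$library$mutations, b$library$mutations)
  expect_identical(a$counts$library, b$counts$library)
  expect_identical(a$counts$day8, b$counts$day8)
  expect_identical(ground_truth(a), ground_truth(b))
})

test_that("selection neutrality: equal rates leave frequencies unchanged", {
  sched <- passage_schedule(duration_days = 8, ceiling = 500,
                            dilution_factor = 0.5, sampling_days = c(2, 8))
  traj <- simulate_selection(rep(0.3, 10), sched, init = 1:10)
  f0 <- (1:10) / sum(1:10)
  for (k in seq_along(traj$sampling_days)) {
    f <- traj$abundance[, k] / sum(traj$abundance[, k])
    expect_equal(f, f0, tolerance = 1e-12)
  }
})

test_that("two-clone selection matches the closed-form exponential ratio", {
  sched <- passage_schedule(duration_days = 8, ceiling = Inf)
  traj <- simulate_selection(c(0.5, 0.0), sched, init = 1)
  a <- traj$abundance[, "day8"]
  expect_equal((a[1] / a[2]), exp(0.5 * 8), tolerance = 1e-10)

  # frequencies are invariant to dilution in deterministic mode
  sched2 <- passage_schedule(duration_days = 8, ceiling = 10,
                             dilution_factor = 0.25)
  traj2 <- simulate_selection(c(0.5, 0.0), sched2, init = 1)
  a2 <- traj2$abundance[, "day8"]
  expect_equal(a2[1] / a2[2], exp(0.5 * 8), tolerance = 1e-10)
})

test_that("stochastic passaging thins clones binomially", {
  sched <- passage_schedule(duration_days = 1, ceiling = 1,
                            dilution_factor = 0.5)
  traj <- simulate_selection(rep(0, 2000), sched, mode = "stochastic",
                             init = 100, seed = 12)
  kept <- traj$abundance[, "day1"]
  expect_true(all(kept == round(kept)))
  expect_lt(abs(mean(kept) - 50), 3 * sqrt(100 * 0.25 / 2000))
})

test_that("schedule validation rejects bad inputs", {
  expect_error(passage_schedule(duration_days = 0), "positive")
  expect_error(passage_schedule(dilution_factor = 0), "0, 1")
  expect_error(passage_schedule(sampling_days = numeric()), "sampling day")
  expect_error(passage_schedule(sampling_days = 99), "within")
})

test_that("simulate_counts: wild-type pool, no error, gives no variant rows", {
  cds <- random_cds(30, seed = 21)
  lib <- simulate_library(cds, mutagenesis_model(0), 5, seed = 1)
  tbl <- simulate_counts(rep(1, 5), lib, cds,
                         sequencing_model(depth = 1000, error_rate = 0),
                         seed = 2)
  expect_equal(nrow(tbl), 0L)
})

test_that("simulate_counts draws binomially at the clone frequency", {
  cds <- random_cds(30, seed = 22)
  bases <- strsplit(cds$sequence, "")[[1]]
  alt <- setdiff(c("A", "C", "G", "T"), bases[10])[1]
  lib <- structure(list(cds_id = cds$id, n_inserts = 4L,
                        mutations = data.frame(insert_id = 1L, pos = 10L,
                                               ref = bases[10], alt = alt,
                                               stringsAsFactors = FALSE)),
                   class = "mutant_library")
  depth <- 1e5
  tbl <- simulate_counts(c(1, 1, 1, 1), lib, cds,
                         sequencing_model(depth = depth, error_rate = 0),
                         seed = 5)
  v <- tbl$variant_reads[tbl$pos == 10L & tbl$alt == alt]
  sigma <- sqrt(0.25 * 0.75 * depth)
  expect_lt(abs(v - 0.25 * depth), 3 * sigma)
  # count conservation: non-reference reads never exceed depth per locus
  per_locus <- tapply(tbl$variant_reads, tbl$pos, sum)
  expect_true(all(per_locus <= depth))
})

test_that("sequencing error spreads reads across the three alternates", {
  cds <- random_cds(40, seed = 23)
  lib <- simulate_library(cds, mutagenesis_model(0), 3, seed = 1)
  e <- 0.003
  depth <- 2e4
  tbl <- simulate_counts(rep(1, 3), lib, cds,
                         sequencing_model(depth = depth, error_rate = e),
                         seed = 7)
  L <- nchar(cds$sequence)
  frac <- sum(tbl$variant_reads) / (depth * L)
  se <- sqrt(e * (1 - e) / (depth * L))
  expect_lt(abs(frac - e), 4 * se)
})

test_that("simulate_counts validates abundances", {
  cds <- random_cds(10, seed = 24)
  lib <- simulate_library(cds, mutagenesis_model(0), 2, seed = 1)
  sm <- sequencing_model(depth = 100)
  expect_error(simulate_counts(c(0, 0), lib, cds, sm), "zero")
  expect_error(simulate_counts(c(-1, 1), lib, cds, sm), "non-negative")
  expect_error(simulate_counts(c(1, 1, 1), lib, cds, sm), "length")
})

test_that("sequencing_model rejects out-of-range parameters", {
  expect_error(sequencing_model(depth = 0), "depth")
  expect_error(sequencing_model(error_rate = 0.02), "error_rate")
})

test_that("ground truth returns the planted set, empty when neutral", {
  cds <- random_cds(60, seed = 25)
  sim <- simulate_screen(cds, n_inserts = 800, n_hits = 3,
                         seqmodel = sequencing_model(depth = 2000),
                         seed = 15)
  gt <- ground_truth(sim)
  expect_equal(nrow(gt), 3L)
  expect_true(all(gt$delta_r == 0.6))
  expect_identical(gt, sim$fitness$effects)

  sim0 <- simulate_screen(cds, n_inserts = 200, n_hits = 0,
                          seqmodel = sequencing_model(depth = 2000),
                          seed = 16)
  expect_equal(nrow(ground_truth(sim0)), 0L)
})

test_that("larger planted advantage gives larger expected fold change", {
  cds <- random_cds(80, seed = 26)
  folds <- vapply(c(0.2, 0.4, 0.6), function(dr) {
    sim <- simulate_screen(cds, n_inserts = 3000, n_hits = 3, delta_r = dr,
                           seqmodel = sequencing_model(depth = 2e4),
                           seed = 55)
    res <- score_screen(sim$counts$library, sim$counts$day8, sim$space,
                        hit_call_params(min_library_reads = 3))
    gt <- ground_truth(sim)
    planted <- paste(res$codon_index, alt_aa_of(res$aa_change)) %in%
      paste(gt$codon_index, gt$alt_aa)
    median(res$fold_change[planted])
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
})
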