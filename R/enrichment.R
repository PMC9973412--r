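# Enrichment scoring: per-variant frequencies, fold change versus the
# plasmid library, exact-test significance with BH FDR control, hit
# calling, and replicate-screen comparison.

#' Variant frequency at a locus
#'
#' The exact ratio of reads supporting the variant to total aligned reads at
#' the locus. No smoothing is applied at this layer; pseudocounts belong to
#' the fold-change policy.
#'
#' @param variant_reads,locus_total_reads Non-negative integer vectors with
#'   `variant_reads <= locus_total_reads`; zero totals are an error.
#' @return Numeric vector of frequencies in `[0, 1]`.
#' @export
variant_frequency <- function(variant_reads, locus_total_reads) {
  if (any(locus_total_reads == 0)) {
    stop("frequency undefined at zero locus coverage", call. = FALSE)
  }
  if (any(variant_reads < 0) || any(variant_reads > locus_total_reads)) {
    stop("need 0 <= variant_reads <= locus_total_reads", call. = FALSE)
  }
  variant_reads / locus_total_reads
}

#' Per-variant enrichment fold change
#'
#' A variant's frequency in the selected pool divided by its frequency in
#' the original plasmid library, computed from read counts. Under the
#' default `"pseudocount"` policy, variants unobserved in the library get a
#' continuity correction of `pseudo` reads added to the variant counts of
#' both samples before forming frequencies, so their fold change stays
#' finite; variants observed in the library use the exact frequency ratio.
#' Under `"strict"`, zero-library variants yield `NA` (the
#' excluded-variant signal), matching a screen restricted to variants
#' present in both samples.
#'
#' @param tp_reads,tp_total Timepoint variant reads and locus total.
#' @param lib_reads,lib_total Library variant reads and locus total.
#' @param policy `"pseudocount"` (default) or `"strict"`.
#' @param pseudo Pseudo-reads added under the pseudocount policy.
#' @return Numeric vector of fold changes (equal frequencies give 1).
#' @examples
#' fold_change(2000, 1e5, 10, 1e5)  # 200
#' @export
fold_change <- function(tp_reads, tp_total, lib_reads, lib_total,
                        policy = c("pseudocount", "strict"), pseudo = 0.5) {
  policy <- match.arg(policy)
  n <- max(length(tp_reads), length(lib_reads))
  tp_reads <- rep_len(tp_reads, n); tp_total <- rep_len(tp_total, n)
  lib_reads <- rep_len(lib_reads, n); lib_total <- rep_len(lib_total, n)
  if (any(tp_total == 0) || any(lib_total == 0)) {
    stop("zero locus coverage", call. = FALSE)
  }
  if (policy == "pseudocount") {
    zero <- lib_reads == 0
    fc <- (tp_reads / tp_total) / (lib_reads / lib_total)
    fc[zero] <- ((tp_reads[zero] + pseudo) / tp_total[zero]) /
      (pseudo / lib_total[zero])
    fc
  } else {
    fc <- (tp_reads / tp_total) / (lib_reads / lib_total)
    fc[lib_reads == 0] <- NA_real_
    fc
  }
}

# log hypergeometric pmf support bounds for a 2x2 table conditioned on
# margins: x successes in the timepoint column
hyper_support <- function(k, n_tp, n_lib) {
  lo <- max(0L, k - n_lib)
  hi <- min(k, n_tp)
  lo:hi
}

#' Exact conditional test for a difference in variant proportions
#'
#' Two-sided exact test on the 2x2 table (variant vs other reads) x
#' (library vs timepoint), conditioning on the margins. The two-sided
#' p-value sums the hypergeometric probabilities of all outcomes no more
#' likely than the observed one (the convention of Fisher's exact test).
#' Because the conditional support has length `lib_reads + tp_reads + 1`,
#' the exact test stays fast even at deep coverage when variant counts are
#' moderate. A pooled two-proportion normal approximation is available for
#' speed at high counts.
#'
#' @param lib_reads,lib_total Library variant reads and locus total.
#' @param tp_reads,tp_total Timepoint variant reads and locus total.
#' @param method `"exact"` (default) or `"approx"`.
#' @return Numeric vector of two-sided p-values.
#' @export
enrichment_test <- function(lib_reads, lib_total, tp_reads, tp_total,
                            method = c("exact", "approx")) {
  method <- match.arg(method)
  n <- max(length(lib_reads), length(tp_reads))
  lib_reads <- rep_len(as.numeric(lib_reads), n)
  lib_total <- rep_len(as.numeric(lib_total), n)
  tp_reads <- rep_len(as.numeric(tp_reads), n)
  tp_total <- rep_len(as.numeric(tp_total), n)
  if (any(lib_total <= 0) || any(tp_total <= 0)) {
    stop("zero read totals", call. = FALSE)
  }
  if (any(lib_reads > lib_total) || any(tp_reads > tp_total) ||
      any(lib_reads < 0) || any(tp_reads < 0)) {
    stop("variant reads must lie in [0, total]", call. = FALSE)
  }
  if (method == "exact") {
    vapply(seq_len(n), function(i) {
      k <- lib_reads[i] + tp_reads[i]
      if (k == 0) return(1)
      supp <- hyper_support(k, tp_total[i], lib_total[i])
      d <- stats::dhyper(supp, m = tp_total[i], n = lib_total[i], k = k)
      d_obs <- d[match(tp_reads[i], supp)]
      min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
    }, numeric(1))
  } else {
    p1 <- lib_reads / lib_total
    p2 <- tp_reads / tp_total
    pp <- (lib_reads + tp_reads) / (lib_total + tp_total)
    se <- sqrt(pp * (1 - pp) * (1 / lib_total + 1 / tp_total))
    z <- ifelse(se == 0, 0, (p2 - p1) / se)
    2 * stats::pnorm(-abs(z))
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment with monotone enforcement; invariant to the input
#' order of the p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed; returned
#'   as `NA` and excluded from the family size).
#' @return q-values in the original order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  o <- order(p[ok], decreasing = TRUE)
  ro <- ok[o]
  q[ro] <- pmin(1, cummin(p[ro] * m / (m:1)))
  q
}

#' Hit-calling thresholds and scoring options
#'
#' @param min_fold_change Minimum enrichment fold change for a hit
#'   (default 50; 47 matches a stricter replicate-screen preset).
#' @param max_q Maximum BH q-value for a hit (default 1e-5).
#' @param min_library_reads Assessability floor on library variant reads.
#'   The default 10 sits ~3x above the expected per-alternate error reads
#'   at the default sequencing model (1e5 depth x 1e-4 error / 3 ~ 3.3), so
#'   "present in the library" means present above the error floor.
#' @param test `"exact"` or `"approx"`, see [enrichment_test()].
#' @param policy,pseudo Fold-change policy, see [fold_change()].
#' @return Object of class `hit_call_params`.
#' @export
hit_call_params <- function(min_fold_change = 50, max_q = 1e-5,
                            min_library_reads = 10,
                            test = c("exact", "approx"),
                            policy = c("pseudocount", "strict"),
                            pseudo = 0.5) {
  if (min_fold_change <= 0) stop("min_fold_change must be > 0", call. = FALSE)
  if (max_q <= 0 || max_q >= 1) stop("max_q must be in (0, 1)", call. = FALSE)
  structure(list(min_fold_change = min_fold_change, max_q = max_q,
                 min_library_reads = as.integer(min_library_reads),
                 test = match.arg(test), policy = match.arg(policy),
                 pseudo = pseudo),
            class = "hit_call_params")
}

#' Score a selection screen against its plasmid library
#'
#' Joins the library and timepoint count tables on `(pos, alt)`, restricts
#' to the assessable set (variants observed in both samples, with library
#' reads at or above the assessability floor), recomputes frequencies from
#' counts, forms fold changes under the pseudocount policy, tests each
#' variant with the exact conditional test, adjusts p-values by
#' Benjamini-Hochberg across the assessable family, and flags hits passing
#' both the fold-change and q-value thresholds.
#'
#' @param library,timepoint [variant_count_table()]s from the same CDS.
#' @param space The [enumerate_snv_space()] result used for amino-acid
#'   annotation and coverage.
#' @param params A [hit_call_params()].
#' @return Object of class `screen_result`: a data frame with one row per
#'   assessable variant (`pos, ref, alt, codon_index, aa_change, effect,
#'   lib_reads, lib_total, tp_reads, tp_total, freq_library, freq_timepoint,
#'   fold_change, p, q, hit`) in `(pos, alt)` order, with attributes
#'   `assessable_n`, `coverage` (vs the space) and `params`. Disjoint
#'   variant sets give an empty result with a warning.
#' @export
score_screen <- function(library, timepoint, space,
                         params = hit_call_params()) {
  stopifnot(inherits(library, "variant_count_table"),
            inherits(timepoint, "variant_count_table"),
            inherits(space, "variant_space"),
            inherits(params, "hit_call_params"))
  lib <- as.data.frame(library)
  tp <- as.data.frame(timepoint)
  key_lib <- paste(lib$pos, lib$alt)
  key_tp <- paste(tp$pos, tp$alt)
  shared <- intersect(key_lib[lib$variant_reads >= max(1L, params$min_library_reads)],
                      key_tp[tp$variant_reads >= 1L])

  empty <- function() {
    res <- data.frame(pos = integer(), ref = character(), alt = character(),
                      codon_index = integer(), aa_change = character(),
                      effect = character(), lib_reads = integer(),
                      lib_total = integer(), tp_reads = integer(),
                      tp_total = integer(), freq_library = numeric(),
                      freq_timepoint = numeric(), fold_change = numeric(),
                      p = numeric(), q = numeric(), hit = logical(),
                      stringsAsFactors = FALSE)
    structure(res, assessable_n = 0L,
              coverage = library_coverage(NULL, NULL, space),
              params = params, class = c("screen_result", "data.frame"))
  }
  if (length(shared) == 0L) {
    warning("library and timepoint share no assessable variants")
    return(empty())
  }

  li <- match(shared, key_lib)
  ti <- match(shared, key_tp)
  if (any(lib$ref[li] != tp$ref[ti])) {
    stop("library and timepoint disagree on a reference base; ",
         "are they from the same CDS?", call. = FALSE)
  }

  nt <- space$nt_variants
  si <- match(shared, paste(nt$pos, nt$alt))
  if (anyNA(si)) {
    stop("counted variant not in the variant space (pos ",
         lib$pos[li[which(is.na(si))[1]]], ")", call. = FALSE)
  }

  res <- data.frame(
    pos = lib$pos[li], ref = lib$ref[li], alt = lib$alt[li],
    codon_index = nt$codon_index[si],
    aa_change = paste0(nt$ref_aa[si], nt$codon_index[si], nt$alt_aa[si]),
    effect = nt$effect[si],
    lib_reads = lib$variant_reads[li], lib_total = lib$locus_total_reads[li],
    tp_reads = tp$variant_reads[ti], tp_total = tp$locus_total_reads[ti],
    stringsAsFactors = FALSE
  )
  res$freq_library <- variant_frequency(res$lib_reads, res$lib_total)
  res$freq_timepoint <- variant_frequency(res$tp_reads, res$tp_total)
  res$fold_change <- fold_change(res$tp_reads, res$tp_total,
                                 res$lib_reads, res$lib_total,
                                 policy = params$policy,
                                 pseudo = params$pseudo)
  res$p <- enrichment_test(res$lib_reads, res$lib_total,
                           res$tp_reads, res$tp_total,
                           method = params$test)
  res$q <- adjust_bh(res$p)
  res$hit <- !is.na(res$fold_change) &
    res$fold_change >= params$min_fold_change & res$q < params$max_q

  res <- res[order(res$pos, res$alt), , drop = FALSE]
  rownames(res) <- NULL
  cov <- library_coverage(res[, c("pos", "alt")], NULL, space)
  structure(res, assessable_n = nrow(res), coverage = cov, params = params,
            class = c("screen_result", "data.frame"))
}

#' @export
print.screen_result <- function(x, ...) {
  cov <- attr(x, "coverage")
  df <- as.data.frame(x)
  cat("<screen_result> ", nrow(df), " assessable variants (",
      cov$aa_pct, "% of ", cov$aa_possible,
      " possible missense+nonsense aa changes), ", sum(df$hit), " hits / ",
      sum(!df$hit), " passengers\n", sep = "")
  if (sum(df$hit) > 0L) {
    hits <- df[df$hit, c("pos", "aa_change", "fold_change", "q")]
    hits <- hits[order(-hits$fold_change), ]
    print(utils::head(hits, 20), row.names = FALSE)
  }
  invisible(x)
}

#' Compare the top hit lists of two screens
#'
#' Ranks each screen's hits by fold change, takes the top `top_n` of each,
#' and intersects them by amino-acid identity.
#'
#' @param result_a,result_b `screen_result` objects (non-empty).
#' @param top_n List length to compare (default 10). Capped with a warning
#'   when a screen has fewer ranked hits.
#' @return List with `top_n_used`, `overlap` (count) and `shared`, a data
#'   frame of shared amino-acid changes with their rank in each screen.
#' @export
compare_screens <- function(result_a, result_b, top_n = 10) {
  if (nrow(result_a) == 0L || nrow(result_b) == 0L) {
    stop("both screen results must be non-empty", call. = FALSE)
  }
  top_list <- function(res) {
    h <- as.data.frame(res)
    h <- h[order(-h$fold_change), , drop = FALSE]
    h[!duplicated(h$aa_change), , drop = FALSE]
  }
  a <- top_list(result_a)
  b <- top_list(result_b)
  n_use <- min(top_n, nrow(a), nrow(b))
  if (n_use < top_n) {
    warning("top_n capped at ", n_use, " (fewer ranked variants available)")
  }
  a_top <- utils::head(a$aa_change, n_use)
  b_top <- utils::head(b$aa_change, n_use)
  shared_aa <- intersect(a_top, b_top)
  shared <- data.frame(aa_change = shared_aa,
                       rank_a = match(shared_aa, a_top),
                       rank_b = match(shared_aa, b_top),
                       stringsAsFactors = FALSE)
  list(top_n_used = n_use, overlap = length(shared_aa), shared = shared)
}

#' Report bundle for a scored screen
#'
#' Assembles the scatter-plot data table (residue position versus fold
#' change, dot size by timepoint variant frequency, hits flagged), the
#' coverage summary versus the space, and the substitution spectrum of the
#' assessable variants.
#'
#' @param records A `screen_result`.
#' @param space The matching [enumerate_snv_space()] result.
#' @return List of class `screen_report` with `scatter`, `coverage`,
#'   `spectrum`, `n_hits`, `n_passengers`.
#' @export
screen_report <- function(records, space) {
  df <- as.data.frame(records)
  scatter <- df[, intersect(c("codon_index", "aa_change", "fold_change",
                              "freq_timepoint", "hit"), names(df)),
                drop = FALSE]
  names(scatter)[names(scatter) == "codon_index"] <- "residue"
  structure(
    list(scatter = scatter,
         coverage = attr(records, "coverage"),
         spectrum = spectrum_table(df),
         n_hits = sum(df$hit),
         n_passengers = sum(!df$hit)),
    class = "screen_report"
  )
}

#' Plot a screen report as a position / fold-change scatter
#'
#' Thin base-graphics layer over the report's scatter table: residue
#' position on x, fold change on y (log scale), point size scaled by
#' timepoint variant frequency, hits in red above the dashed threshold line.
#'
#' @param report A [screen_report()].
#' @param threshold Horizontal cutoff line (default 50).
#' @param ... Passed to [plot()].
#' @return The report, invisibly.
#' @export
plot_screen <- function(report, threshold = 50, ...) {
  s <- report$scatter
  if (nrow(s) == 0L) {
    warning("empty report; nothing to plot")
    return(invisible(report))
  }
  cex <- 0.3 + 2 * sqrt(s$freq_timepoint / max(s$freq_timepoint, na.rm = TRUE))
  plot(s$residue, pmax(s$fold_change, 1e-3), log = "y",
       xlab = "residue position", ylab = "fold change",
       col = ifelse(s$hit, "red", grDevices::adjustcolor("grey40", 0.5)),
       pch = 16, cex = cex, ...)
  graphics::abline(h = threshold, lty = 2)
  invisible(report)
}
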