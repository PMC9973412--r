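# Enumeration and classification of the single-nucleotide substitution
# space of a coding sequence, plus coverage and spectrum summaries.

#' Classify a base substitution as transition or transversion
#'
#' Purine<->purine (A/G) and pyrimidine<->pyrimidine (C/T) changes are
#' transitions; purine<->pyrimidine changes are transversions.
#'
#' @param ref_base,alt_base Character vectors over `{A,C,G,T}`; recycled to a
#'   common length. `ref_base[i]` must differ from `alt_base[i]`.
#' @return Character vector of `"transition"` / `"transversion"`.
#' @examples
#' classify_substitution("A", "G")  # transition
#' classify_substitution("C", "A")  # transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  n <- max(length(ref_base), length(alt_base))
  ref_base <- rep_len(toupper(ref_base), n)
  alt_base <- rep_len(toupper(alt_base), n)
  if (!all(ref_base %in% DNA_BASES) || !all(alt_base %in% DNA_BASES)) {
    stop("bases must be one of A/C/G/T", call. = FALSE)
  }
  if (any(ref_base == alt_base)) {
    stop("ref and alt base must differ", call. = FALSE)
  }
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  unname(ifelse(purine[ref_base] == purine[alt_base],
                "transition", "transversion"))
}

classify_effect <- function(ref_aa, alt_aa) {
  # Synonymous covers stop->stop; stop_altering is a read-through of the
  # terminal stop; nonsense introduces a premature stop.
  ifelse(ref_aa == alt_aa, "synonymous",
    ifelse(ref_aa == "*", "stop_altering",
      ifelse(alt_aa == "*", "nonsense", "missense")))
}

EFFECT_CLASSES <- c("synonymous", "missense", "nonsense", "stop_altering")

#' Enumerate the complete single-nucleotide substitution space of a CDS
#'
#' For every enumerated position of the coding sequence, generates the three
#' possible substitutions, maps each to its codon-level amino-acid change
#' under the standard genetic code, and classifies both the substitution
#' (transition/transversion) and the protein effect (synonymous, missense,
#' nonsense, stop_altering). Amino-acid changes are additionally deduplicated
#' to the set of distinct `(codon_index, alt_aa)` pairs reachable by one
#' substitution — the denominator used for amino-acid-level coverage.
#'
#' @param cds A [coding_sequence()].
#' @param include_stop_codon When the CDS carries a terminal stop codon,
#'   should its three positions be enumerated? Substitutions in the stop codon
#'   are classed `stop_altering` (or `synonymous` when the altered codon is
#'   still a stop). Defaults to `TRUE`: the stop codon is part of the
#'   mutagenized insert, but its variants are never counted in the
#'   missense+nonsense totals.
#' @return An object of class `variant_space`: list with `cds_id`,
#'   `nt_variants` (data frame, 3 rows per enumerated base: `pos`, `ref`,
#'   `alt`, `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `effect`, `subst_class`), `aa_changes` (deduplicated data frame:
#'   `codon_index`, `ref_aa`, `alt_aa`, `effect`, `n_nt_routes`), `counts`
#'   (effect-class totals at both levels) and `length_enumerated`.
#' @examples
#' sp <- enumerate_snv_space(coding_sequence("ATGTAA"), include_stop_codon = FALSE)
#' nrow(sp$nt_variants)  # 9
#' @export
enumerate_snv_space <- function(cds, include_stop_codon = TRUE) {
  stopifnot(inherits(cds, "coding_sequence"))
  bases <- cds_bases(cds)
  L_full <- length(bases)
  L <- if (cds$includes_stop && !include_stop_codon) L_full - 3L else L_full
  if (L <= 0L) stop("nothing to enumerate", call. = FALSE)

  pos <- rep(seq_len(L), each = 3L)
  ref <- bases[pos]
  # the three alternates of each reference base, in A<C<G<T order
  alt_of <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
  alt <- unlist(alt_of[bases[seq_len(L)]], use.names = FALSE)

  codon_index <- (pos - 1L) %/% 3L + 1L
  codons <- cds_codons(cds)
  ref_codon <- codons[codon_index]
  offset <- (pos - 1L) %% 3L + 1L
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt

  ref_aa <- translate_codons(ref_codon)
  alt_aa <- translate_codons(alt_codon)
  effect <- classify_effect(ref_aa, alt_aa)
  subst_class <- classify_substitution(ref, alt)

  nt <- data.frame(pos = pos, ref = ref, alt = alt,
                   codon_index = codon_index,
                   ref_codon = ref_codon, alt_codon = alt_codon,
                   ref_aa = ref_aa, alt_aa = alt_aa,
                   effect = effect, subst_class = subst_class,
                   stringsAsFactors = FALSE)

  # deduplicate to distinct (codon_index, alt_aa) pairs
  key <- paste(codon_index, alt_aa, sep = ":")
  first <- !duplicated(key)
  aa <- data.frame(codon_index = codon_index[first], ref_aa = ref_aa[first],
                   alt_aa = alt_aa[first], effect = effect[first],
                   n_nt_routes = as.integer(table(key)[key[first]]),
                   stringsAsFactors = FALSE)
  aa <- aa[order(aa$codon_index, aa$alt_aa), , drop = FALSE]
  rownames(aa) <- NULL

  count_by <- function(eff) {
    out <- integer(length(EFFECT_CLASSES))
    names(out) <- EFFECT_CLASSES
    tab <- table(factor(eff, levels = EFFECT_CLASSES))
    out[names(tab)] <- as.integer(tab)
    out
  }
  counts <- list(
    nt = count_by(nt$effect),
    aa = count_by(aa$effect),
    nt_total = nrow(nt),
    aa_total = nrow(aa)
  )
  counts$nt_missense_nonsense <- sum(counts$nt[c("missense", "nonsense")])
  counts$aa_missense_nonsense <- sum(counts$aa[c("missense", "nonsense")])

  structure(
    list(cds_id = cds$id, cds = cds, nt_variants = nt, aa_changes = aa,
         counts = counts, length_enumerated = L),
    class = "variant_space"
  )
}

#' @export
print.variant_space <- function(x, ...) {
  cat("<variant_space> ", x$cds_id, ": ", x$length_enumerated,
      " bp enumerated, ", nrow(x$nt_variants), " nt variants, ",
      nrow(x$aa_changes), " distinct aa changes (",
      x$counts$aa_missense_nonsense, " missense+nonsense)\n", sep = "")
  print(rbind(nt = x$counts$nt, aa = x$counts$aa))
  invisible(x)
}

#' Tabulate the substitution spectrum of a variant collection
#'
#' Counts each of the 12 ordered base substitutions (A>C ... T>G) and the
#' marginal transition / transversion totals.
#'
#' @param variants Data frame with columns `ref` and `alt` (e.g. the
#'   `nt_variants` of a [enumerate_snv_space()] result, or any subset).
#' @return Object of class `spectrum_table`: list with `counts` (named
#'   12-vector), `transitions`, `transversions`, `total`.
#' @export
spectrum_table <- function(variants) {
  subs <- outer(DNA_BASES, DNA_BASES, paste, sep = ">")
  subs <- subs[row(subs) != col(subs)]
  subs <- sort(subs)
  counts <- integer(length(subs))
  names(counts) <- subs
  if (nrow(variants) > 0L) {
    obs <- table(paste(variants$ref, variants$alt, sep = ">"))
    if (!all(names(obs) %in% subs)) {
      stop("invalid substitution label: ",
           setdiff(names(obs), subs)[1], call. = FALSE)
    }
    counts[names(obs)] <- as.integer(obs)
  }
  pieces <- strsplit(subs, ">", fixed = TRUE)
  is_ts <- vapply(pieces, function(p) {
    classify_substitution(p[1], p[2]) == "transition"
  }, logical(1))
  structure(
    list(counts = counts,
         transitions = sum(counts[is_ts]),
         transversions = sum(counts[!is_ts]),
         total = sum(counts)),
    class = "spectrum_table"
  )
}

#' @export
print.spectrum_table <- function(x, ...) {
  cat("<spectrum_table> total =", x$total,
      "| transitions =", x$transitions,
      "| transversions =", x$transversions, "\n")
  print(x$counts)
  invisible(x)
}

#' Percentage coverage to one decimal place
#'
#' `100 * observed / possible`, rounded to one decimal — the reporting
#' convention used throughout the package's coverage summaries.
#'
#' @param n_observed,n_possible Non-negative counts, `n_possible > 0`.
#' @return Numeric percentage rounded to one decimal.
#' @examples
#' coverage_percent(8386, 11638)  # 72.1
#' @export
coverage_percent <- function(n_observed, n_possible) {
  if (any(n_possible <= 0)) stop("n_possible must be positive", call. = FALSE)
  round(100 * n_observed / n_possible, 1)
}

#' Library coverage of a variant space
#'
#' Compares the observed nucleotide variants and amino-acid changes of a
#' sequenced library against the theoretical space: unique nucleotide
#' variants over 3L, and distinct missense+nonsense amino-acid changes over
#' the theoretical missense+nonsense total. Observations not contained in the
#' space are reported as rejects (with a reason), never silently dropped.
#'
#' @param observed_nt Data frame with columns `pos`, `alt` (optionally `ref`),
#'   one row per observed nucleotide variant, or `NULL`.
#' @param observed_aa Data frame with columns `codon_index`, `alt_aa`, or
#'   `NULL` to derive the amino-acid set from `observed_nt`.
#' @param space A [enumerate_snv_space()] result.
#' @return List with `nt_observed`, `nt_possible`, `nt_pct`, `aa_observed`,
#'   `aa_possible`, `aa_pct` (percentages to one decimal; amino-acid level
#'   restricted to missense+nonsense changes) and a `rejects` data frame.
#' @export
library_coverage <- function(observed_nt, observed_aa = NULL, space) {
  stopifnot(inherits(space, "variant_space"))
  nt <- space$nt_variants
  nt_key <- paste(nt$pos, nt$alt, sep = ":")
  rejects <- data.frame(level = character(), key = character(),
                        reason = character(), stringsAsFactors = FALSE)

  nt_observed <- 0L
  if (!is.null(observed_nt) && nrow(observed_nt) > 0L) {
    obs_key <- unique(paste(observed_nt$pos, observed_nt$alt, sep = ":"))
    ok <- obs_key %in% nt_key
    if (any(!ok)) {
      rejects <- rbind(rejects, data.frame(
        level = "nt", key = obs_key[!ok],
        reason = "not in variant space (position/alt outside enumerated CDS)",
        stringsAsFactors = FALSE))
    }
    nt_observed <- sum(ok)
  }

  aa <- space$aa_changes
  aa_mn <- aa[aa$effect %in% c("missense", "nonsense"), , drop = FALSE]
  aa_key <- paste(aa$codon_index, aa$alt_aa, sep = ":")
  aa_mn_key <- paste(aa_mn$codon_index, aa_mn$alt_aa, sep = ":")

  if (is.null(observed_aa) && !is.null(observed_nt) && nrow(observed_nt) > 0L) {
    obs_key <- unique(paste(observed_nt$pos, observed_nt$alt, sep = ":"))
    hit <- match(obs_key, nt_key)
    hit <- hit[!is.na(hit)]
    observed_aa <- unique(nt[hit, c("codon_index", "alt_aa")])
  }

  aa_observed <- 0L
  if (!is.null(observed_aa) && nrow(observed_aa) > 0L) {
    obs_key <- unique(paste(observed_aa$codon_index, observed_aa$alt_aa,
                            sep = ":"))
    unknown <- !obs_key %in% aa_key
    if (any(unknown)) {
      rejects <- rbind(rejects, data.frame(
        level = "aa", key = obs_key[unknown],
        reason = "amino-acid change not reachable by one substitution",
        stringsAsFactors = FALSE))
    }
    aa_observed <- sum(obs_key %in% aa_mn_key)
  }

  list(
    nt_observed = nt_observed,
    nt_possible = nrow(nt),
    nt_pct = coverage_percent(nt_observed, nrow(nt)),
    aa_observed = aa_observed,
    aa_possible = nrow(aa_mn),
    aa_pct = coverage_percent(aa_observed, nrow(aa_mn)),
    rejects = rejects
  )
}

#' Expected number of coding changes per mutagenized insert
#'
#' Converts a nucleotide mutation rate (mean substitutions per insert) to an
#' expected number of amino-acid-changing (missense or nonsense) variants per
#' insert by multiplying with the ratio of distinct amino-acid-level
#' missense+nonsense changes to the nucleotide-level space size. With a rate
#' of 2.59 and the canonical 8,065 / 11,638 space this gives 1.79 coding
#' variants per polypeptide.
#'
#' @param nt_rate Mean nucleotide substitutions per insert (>= 0).
#' @param space A [enumerate_snv_space()] result, or `NULL` when explicit
#'   counts are supplied.
#' @param n_aa_changes,n_nt_variants Explicit space counts overriding `space`
#'   (amino-acid-level missense+nonsense total and nucleotide-level total).
#' @return Expected coding variants per insert.
#' @examples
#' expected_coding_changes_per_insert(2.59, n_aa_changes = 8065,
#'                                    n_nt_variants = 11638)
#' @export
expected_coding_changes_per_insert <- function(nt_rate, space = NULL,
                                               n_aa_changes = NULL,
                                               n_nt_variants = NULL) {
  if (nt_rate < 0) stop("nt_rate must be non-negative", call. = FALSE)
  if (is.null(n_aa_changes) || is.null(n_nt_variants)) {
    if (is.null(space)) stop("supply a variant space or explicit counts",
                             call. = FALSE)
    n_aa_changes <- space$counts$aa_missense_nonsense
    n_nt_variants <- space$counts$nt_total
  }
  if (n_nt_variants <= 0) stop("empty variant space", call. = FALSE)
  nt_rate * n_aa_changes / n_nt_variants
}

#' Export a variant space as TSV
#'
#' Writes the full nucleotide-variant table with columns `pos`, `ref`, `alt`,
#' `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`, `effect`,
#' `subst_class`.
#'
#' @param space A [enumerate_snv_space()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_space <- function(space, path) {
  utils::write.table(space$nt_variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
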