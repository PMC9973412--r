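# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: enumeration is a plain nested loop, the exact
# test is a log-choose hypergeometric summation, BH is the textbook step-up.

# Brute-force SNV enumeration: loop over positions x 3 alternates,
# translate both codons with a locally built codon table.
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(
    as.vector(t(outer(bases, bases, paste0))), bases, paste0)))
  stats::setNames(aas, codons)
})

oracle_snv_space <- function(sequence, include_stop_codon = TRUE) {
  seqv <- strsplit(toupper(sequence), "")[[1]]
  last_codon <- paste(seqv[(length(seqv) - 2):length(seqv)], collapse = "")
  L <- length(seqv)
  if (!include_stop_codon && oracle_codon_table[last_codon] == "*") {
    L <- L - 3L
  }
  rows <- list()
  for (pos in seq_len(L)) {
    for (alt in setdiff(c("A", "C", "G", "T"), seqv[pos])) {
      ci <- (pos - 1) %/% 3 + 1
      ref_codon <- paste(seqv[(3 * ci - 2):(3 * ci)], collapse = "")
      alt_seq <- seqv
      alt_seq[pos] <- alt
      alt_codon <- paste(alt_seq[(3 * ci - 2):(3 * ci)], collapse = "")
      ra <- unname(oracle_codon_table[ref_codon])
      aa <- unname(oracle_codon_table[alt_codon])
      effect <- if (ra == aa) "synonymous" else if (ra == "*") {
        "stop_altering"
      } else if (aa == "*") "nonsense" else "missense"
      is_ts <- paste0(seqv[pos], alt) %in% c("AG", "GA", "CT", "TC")
      rows[[length(rows) + 1]] <- data.frame(
        pos = as.integer(pos), ref = seqv[pos], alt = alt,
        codon_index = as.integer(ci),
        ref_codon = ref_codon, alt_codon = alt_codon,
        ref_aa = ra, alt_aa = aa, effect = effect,
        subst_class = if (is_ts) "transition" else "transversion",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

oracle_aa_changes <- function(nt) {
  unique(nt[, c("codon_index", "alt_aa", "effect")])
}

# Two-sided Fisher p by explicit log-choose summation over the whole
# conditional support, independent of dhyper.
oracle_fisher_p <- function(lib_reads, lib_total, tp_reads, tp_total) {
  k <- lib_reads + tp_reads
  if (k == 0) return(1)
  supp <- max(0, k - lib_total):min(k, tp_total)
  logp <- lchoose(tp_total, supp) + lchoose(lib_total, k - supp) -
    lchoose(lib_total + tp_total, k)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(tp_reads, supp)]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Textbook BH step-up: q_(i) = min_{j >= i} p_(j) * m / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Convenience count-table builder
make_counts <- function(pos, ref, alt, v, tot, id = "s") {
  variant_count_table(
    data.frame(pos = pos, ref = ref, alt = alt, variant_reads = v,
               locus_total_reads = tot, stringsAsFactors = FALSE),
    sample_id = id)
}

# alt amino acid from an aa_change label like "E715K"
alt_aa_of <- function(aa_change) sub("^[A-Z*][0-9]+", "", aa_change)
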