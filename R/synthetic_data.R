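# Synthetic screens with known ground truth: error-prone PCR libraries,
# clonal selection under per-variant fitness effects, and multinomial
# sequencing of the pool.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

SPECTRUM_LABELS <- sort(c(outer(DNA_BASES, DNA_BASES, paste, sep = ">"))[
  c(outer(DNA_BASES, DNA_BASES, "!="))])

#' Error-prone PCR mutagenesis model
#'
#' Substitution load per insert is Poisson; positions are uniform over the
#' CDS; the alternate base at a mutated position is drawn from a 12-cell
#' ordered-substitution spectrum conditioned on the reference base.
#'
#' @param mean_mutations Poisson mean substitutions per insert. Libraries of
#'   the kind this models run at roughly 2.1-2.6 changes per ~3.9 kb insert;
#'   the default is 2.59.
#' @param spectrum_weights Named non-negative weights for the 12 ordered
#'   substitutions (`"A>C"` ... `"T>G"`); `NULL` means uniform. Normalized
#'   internally.
#' @return Object of class `mutagenesis_model`.
#' @export
mutagenesis_model <- function(mean_mutations = 2.59, spectrum_weights = NULL) {
  if (mean_mutations < 0) stop("mean_mutations must be >= 0", call. = FALSE)
  if (is.null(spectrum_weights)) {
    spectrum_weights <- stats::setNames(rep(1, 12), SPECTRUM_LABELS)
  }
  if (!setequal(names(spectrum_weights), SPECTRUM_LABELS)) {
    stop("spectrum_weights must be named by the 12 ordered substitutions",
         call. = FALSE)
  }
  if (any(spectrum_weights < 0) || sum(spectrum_weights) == 0) {
    stop("spectrum_weights must be non-negative and not all zero",
         call. = FALSE)
  }
  spectrum_weights <- spectrum_weights[SPECTRUM_LABELS]
  spectrum_weights <- spectrum_weights / sum(spectrum_weights)
  structure(list(mean_mutations = mean_mutations,
                 spectrum_weights = spectrum_weights),
            class = "mutagenesis_model")
}

#' Simulate an error-prone PCR mutant library
#'
#' Draws `n_inserts` independent inserts. Each insert receives a
#' Poisson-distributed number of substitutions at distinct uniform positions
#' (at most one variant per position, in cis on the same molecule), with
#' alternate bases drawn from the model's spectrum conditioned on the
#' reference base.
#'
#' @param cds A [coding_sequence()].
#' @param model A [mutagenesis_model()].
#' @param n_inserts Number of inserts (>= 1).
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @return Object of class `mutant_library`: list with `cds_id`, `n_inserts`
#'   and `mutations`, a data frame `(insert_id, pos, ref, alt)` holding every
#'   substitution; inserts absent from the table are wild type.
#' @export
simulate_library <- function(cds, model, n_inserts, seed = NULL) {
  stopifnot(inherits(cds, "coding_sequence"),
            inherits(model, "mutagenesis_model"))
  if (n_inserts < 1L) stop("n_inserts must be >= 1", call. = FALSE)
  bases <- cds_bases(cds)
  L <- length(bases)

  # P(alt | ref) from the 12-cell spectrum
  w <- model$spectrum_weights
  alt_prob <- lapply(DNA_BASES, function(b) {
    alts <- setdiff(DNA_BASES, b)
    p <- w[paste(b, alts, sep = ">")]
    if (sum(p) == 0) p <- rep(1, 3)
    stats::setNames(p / sum(p), alts)
  })
  names(alt_prob) <- DNA_BASES

  mutations <- with_seed(seed, {
    n_mut <- stats::rpois(n_inserts, model$mean_mutations)
    n_mut <- pmin(n_mut, L)  # distinct positions cannot exceed CDS length
    total <- sum(n_mut)
    if (total == 0L) {
      data.frame(insert_id = integer(), pos = integer(),
                 ref = character(), alt = character(),
                 stringsAsFactors = FALSE)
    } else {
      ids <- rep.int(seq_len(n_inserts), n_mut)
      pos <- unlist(lapply(n_mut[n_mut > 0L], function(k) {
        sample.int(L, k)
      }), use.names = FALSE)
      ref <- bases[pos]
      # draw alternates per reference base in one vectorized pass per base
      alt <- character(total)
      for (b in DNA_BASES) {
        idx <- which(ref == b)
        if (length(idx) > 0L) {
          p <- alt_prob[[b]]
          alt[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
        }
      }
      data.frame(insert_id = ids, pos = pos, ref = ref, alt = alt,
                 stringsAsFactors = FALSE)
    }
  })
  structure(list(cds_id = cds$id, n_inserts = as.integer(n_inserts),
                 mutations = mutations),
            class = "mutant_library")
}

#' @export
print.mutant_library <- function(x, ...) {
  cat("<mutant_library> ", x$n_inserts, " inserts of ", x$cds_id, ", ",
      nrow(x$mutations), " substitutions (",
      format(nrow(x$mutations) / x$n_inserts, digits = 3),
      " per insert)\n", sep = "")
  invisible(x)
}

#' Per-variant fitness model for clonal selection
#'
#' Fitness acts at the level of the amino-acid change: an insert's net growth
#' rate is the baseline plus a combination of the rate modifiers of the
#' amino-acid changes it carries. Changes without an entry in `effects` are
#' passengers (modifier 0).
#'
#' @param baseline_rate Wild-type net growth rate per day under the selection
#'   ligand. The default 0 models a pool that is static without an
#'   activating variant (survival signaling but no IL3).
#' @param effects Data frame `(codon_index, alt_aa, delta_r)` of growth-rate
#'   modifiers per day, or `NULL` for an all-neutral pool.
#' @param combine How modifiers combine within a multi-mutant insert:
#'   `"max"` (default; one sufficient activating change sets the clone's
#'   rate) or `"sum"`.
#' @param nonsense_penalty Optional growth-rate penalty (<= 0) added when the
#'   insert carries any nonsense variant; `NULL` disables it.
#' @return Object of class `fitness_model`.
#' @export
fitness_model <- function(baseline_rate = 0, effects = NULL,
                          combine = c("max", "sum"),
                          nonsense_penalty = NULL) {
  combine <- match.arg(combine)
  if (is.null(effects)) {
    effects <- data.frame(codon_index = integer(), alt_aa = character(),
                          delta_r = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("codon_index", "alt_aa", "delta_r") %in% names(effects)))
  if (any(!is.finite(effects$delta_r))) {
    stop("fitness effects must be finite", call. = FALSE)
  }
  if (!is.null(nonsense_penalty) && nonsense_penalty > 0) {
    stop("nonsense_penalty must be <= 0", call. = FALSE)
  }
  structure(list(baseline_rate = baseline_rate, effects = effects,
                 combine = combine, nonsense_penalty = nonsense_penalty),
            class = "fitness_model")
}

#' Resolve per-insert growth rates
#'
#' Maps each insert's nucleotide variants to amino-acid changes through the
#' variant space, looks up their fitness modifiers, and combines them
#' according to the model's rule.
#'
#' @param library A [simulate_library()] result.
#' @param space The matching [enumerate_snv_space()] result.
#' @param fitness A [fitness_model()].
#' @return Numeric vector of net growth rates per day, one per insert.
#' @export
clone_growth_rates <- function(library, space, fitness) {
  stopifnot(inherits(library, "mutant_library"),
            inherits(space, "variant_space"),
            inherits(fitness, "fitness_model"))
  mut <- library$mutations
  rates <- rep(fitness$baseline_rate, library$n_inserts)
  if (nrow(mut) == 0L) return(rates)

  nt <- space$nt_variants
  idx <- match(paste(mut$pos, mut$alt), paste(nt$pos, nt$alt))
  if (anyNA(idx)) {
    stop("library contains a variant outside the variant space (pos ",
         mut$pos[which(is.na(idx))[1]], ")", call. = FALSE)
  }
  aa_key <- paste(nt$codon_index[idx], nt$alt_aa[idx])
  eff <- fitness$effects
  delta <- eff$delta_r[match(aa_key, paste(eff$codon_index, eff$alt_aa))]
  delta[is.na(delta)] <- 0

  agg_fun <- if (fitness$combine == "max") max else sum
  by_insert <- tapply(delta, mut$insert_id, agg_fun)
  ids <- as.integer(names(by_insert))
  if (fitness$combine == "max") {
    rates[ids] <- rates[ids] + pmax(as.numeric(by_insert), 0)
  } else {
    rates[ids] <- rates[ids] + as.numeric(by_insert)
  }
  if (!is.null(fitness$nonsense_penalty)) {
    has_nonsense <- tapply(nt$effect[idx] == "nonsense", mut$insert_id, any)
    pen_ids <- as.integer(names(has_nonsense))[as.logical(has_nonsense)]
    rates[pen_ids] <- rates[pen_ids] + fitness$nonsense_penalty
  }
  rates
}

#' Passaging schedule for a selection culture
#'
#' @param duration_days Length of the selection (default 8 days).
#' @param ceiling Pool-size ceiling triggering a passage.
#' @param dilution_factor Fraction of cells kept at each passage, in (0, 1].
#' @param sampling_days Days at which count tables are drawn (default: the
#'   final day). Must be non-empty.
#' @return Object of class `passage_schedule`.
#' @export
passage_schedule <- function(duration_days = 8, ceiling = 1e7,
                             dilution_factor = 0.1,
                             sampling_days = duration_days) {
  if (duration_days <= 0) stop("duration_days must be positive", call. = FALSE)
  if (dilution_factor <= 0 || dilution_factor > 1) {
    stop("dilution_factor must be in (0, 1]", call. = FALSE)
  }
  if (length(sampling_days) == 0L) {
    stop("schedule needs at least one sampling day", call. = FALSE)
  }
  if (any(sampling_days < 0 | sampling_days > duration_days)) {
    stop("sampling_days must lie within [0, duration_days]", call. = FALSE)
  }
  structure(list(duration_days = duration_days, ceiling = ceiling,
                 dilution_factor = dilution_factor,
                 sampling_days = sort(unique(sampling_days))),
            class = "passage_schedule")
}

#' Simulate clonal selection dynamics
#'
#' Each clone grows exponentially, `a_i(t) = a_i(0) exp(r_i t)`, stepped in
#' whole days. When the pool exceeds the schedule's ceiling, a passage
#' rescales every clone by the dilution factor — deterministically in
#' `"deterministic"` mode (relative frequencies are then invariant to
#' dilution) or by per-clone binomial thinning in `"stochastic"` mode.
#'
#' @param rates Per-clone net growth rates per day ([clone_growth_rates()]).
#' @param schedule A [passage_schedule()].
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param init Initial per-clone abundance; scalar or vector (default 100
#'   cells per clone, so stochastic thinning has integer-sized clones).
#' @param seed Optional seed (stochastic mode).
#' @return Object of class `selection_trajectories`: list with
#'   `sampling_days` and `abundance`, a clones x sampling-days matrix.
#' @export
simulate_selection <- function(rates, schedule, mode = c("deterministic",
                                                         "stochastic"),
                               init = 100, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "passage_schedule"))
  if (any(!is.finite(rates))) stop("growth rates must be finite", call. = FALSE)
  n <- length(rates)
  a <- rep_len(init, n)
  days <- schedule$sampling_days
  out <- matrix(NA_real_, nrow = n, ncol = length(days),
                dimnames = list(NULL, paste0("day", days)))
  with_seed(seed, {
    growth <- exp(rates)
    t <- 0L
    if (0 %in% days) out[, match(0, days)] <- a
    while (t < schedule$duration_days) {
      t <- t + 1L
      a <- a * growth
      if (sum(a) > schedule$ceiling) {
        if (mode == "deterministic") {
          a <- a * schedule$dilution_factor
        } else {
          a <- stats::rbinom(n, size = round(a),
                             prob = schedule$dilution_factor)
        }
      }
      if (t %in% days) out[, match(t, days)] <- a
    }
  })
  structure(list(sampling_days = days, abundance = out),
            class = "selection_trajectories")
}

#' Deep-sequencing model for count sampling
#'
#' @param depth Aligned reads per locus (order 1e4-1e5, emulating deep
#'   amplicon coverage; default 1e5).
#' @param error_rate Per-base miscall rate after quality filtering; must be
#'   below 0.01 (default 1e-4). A miscalled read lands uniformly on one of
#'   the three alternates.
#' @return Object of class `sequencing_model`.
#' @export
sequencing_model <- function(depth = 1e5, error_rate = 1e-4) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.01) {
    stop("error_rate must be in [0, 0.01)", call. = FALSE)
  }
  structure(list(depth = as.integer(depth), error_rate = error_rate),
            class = "sequencing_model")
}

#' Sample per-variant read counts from a clone pool
#'
#' At every CDS locus, `depth` reads are drawn multinomially from the clone
#' frequency vector: a clone contributes its alternate base at loci it
#' mutates and the reference base elsewhere. Sequencing error flips each
#' read's base to a uniform alternate at the model's error rate. Per-locus
#' counts always sum to the depth; the emitted table lists the non-reference
#' rows with reads.
#'
#' @param abundance Non-negative per-clone abundances (not all zero).
#' @param library The [simulate_library()] result the abundances refer to.
#' @param cds The [coding_sequence()].
#' @param seqmodel A [sequencing_model()].
#' @param sample_id Label for the emitted table.
#' @param seed Optional seed.
#' @return A [variant_count_table()] with one row per (pos, alt) observed
#'   with at least one read.
#' @export
simulate_counts <- function(abundance, library, cds, seqmodel,
                            sample_id = "sample", seed = NULL) {
  stopifnot(inherits(library, "mutant_library"),
            inherits(cds, "coding_sequence"),
            inherits(seqmodel, "sequencing_model"))
  if (length(abundance) != library$n_inserts) {
    stop("abundance length must equal the library's insert count",
         call. = FALSE)
  }
  if (any(abundance < 0)) stop("abundances must be non-negative", call. = FALSE)
  total <- sum(abundance)
  if (total == 0) stop("total abundance is zero", call. = FALSE)
  freq <- abundance / total

  bases <- cds_bases(cds)
  L <- length(bases)
  mut <- library$mutations

  # 4 x L matrix of true base frequencies in the pool
  P <- matrix(0, nrow = 4L, ncol = L, dimnames = list(DNA_BASES, NULL))
  if (nrow(mut) > 0L) {
    f_mut <- freq[mut$insert_id]
    keep <- f_mut > 0
    if (any(keep)) {
      cell <- paste(mut$alt[keep], mut$pos[keep])
      contrib <- tapply(f_mut[keep], cell, sum)
      parts <- strsplit(names(contrib), " ", fixed = TRUE)
      alt_i <- match(vapply(parts, `[[`, "", 1L), DNA_BASES)
      pos_i <- as.integer(vapply(parts, `[[`, "", 2L))
      P[cbind(alt_i, pos_i)] <- as.numeric(contrib)
    }
  }
  ref_i <- match(bases, DNA_BASES)
  P[cbind(ref_i, seq_len(L))] <- pmax(0, 1 - colSums(P))

  e <- seqmodel$error_rate
  if (e > 0) P <- P * (1 - e) + (e / 3) * (1 - P)

  depth <- seqmodel$depth
  counts <- with_seed(seed, {
    vapply(seq_len(L), function(j) {
      stats::rmultinom(1L, depth, P[, j])[, 1L]
    }, integer(4L))
  })
  # drop the reference row at each locus, keep non-zero alternates
  counts[cbind(ref_i, seq_len(L))] <- 0L
  nz <- which(counts > 0L, arr.ind = TRUE)
  df <- data.frame(pos = as.integer(nz[, "col"]),
                   ref = bases[nz[, "col"]],
                   alt = DNA_BASES[nz[, "row"]],
                   variant_reads = counts[nz],
                   locus_total_reads = rep(depth, nrow(nz)),
                   stringsAsFactors = FALSE)
  variant_count_table(df, sample_id = sample_id)
}

#' Simulate a complete selection screen with known ground truth
#'
#' Orchestrates the full synthetic experiment: mutagenized library,
#' planted activating amino-acid changes, clonal selection, and multinomial
#' sequencing of the plasmid library (day 0, equal clone abundances) and of
#' the selected pool at each sampling day.
#'
#' @param cds A [coding_sequence()].
#' @param n_inserts Library complexity (independent inserts). The default
#'   50,000 is a desk-scale stand-in for the millions of transduced cells of
#'   a real screen; it keeps each variant on ~10 independent inserts so that
#'   in-cis passenger hitchhiking stays diluted, as it is at full scale.
#' @param mut_model A [mutagenesis_model()].
#' @param n_hits Number of activating amino-acid changes to plant; drawn
#'   uniformly from the missense changes actually present in the library
#'   (a variant absent from the library cannot be selected).
#' @param delta_r Growth-rate advantage per day of each planted change. The
#'   default 0.6/day puts the expected 8-day enrichment near exp(4.8) ~ 120,
#'   inside the 57-464-fold band typical of true activating variants.
#' @param schedule A [passage_schedule()].
#' @param seqmodel A [sequencing_model()].
#' @param mode Selection mode, see [simulate_selection()].
#' @param seed Integer seed driving the whole simulation.
#' @return Object of class `screen_simulation`: list with `cds`, `space`,
#'   `library`, `fitness`, `rates`, `trajectories`, `counts` (element
#'   `library` plus one `variant_count_table` per sampling day) and
#'   `ground_truth` (data frame `codon_index`, `alt_aa`, `delta_r`).
#' @export
simulate_screen <- function(cds,
                            n_inserts = 50000,
                            mut_model = mutagenesis_model(),
                            n_hits = 10,
                            delta_r = 0.6,
                            schedule = passage_schedule(),
                            seqmodel = sequencing_model(),
                            mode = "deterministic",
                            seed = NULL) {
  space <- enumerate_snv_space(cds)
  sim <- with_seed(seed, {
    library <- simulate_library(cds, mut_model, n_inserts)

    # plant activators among missense changes present in the library
    truth <- data.frame(codon_index = integer(), alt_aa = character(),
                        delta_r = numeric(), stringsAsFactors = FALSE)
    if (n_hits > 0L && nrow(library$mutations) > 0L) {
      nt <- space$nt_variants
      idx <- match(paste(library$mutations$pos, library$mutations$alt),
                   paste(nt$pos, nt$alt))
      present <- unique(data.frame(codon_index = nt$codon_index[idx],
                                   alt_aa = nt$alt_aa[idx],
                                   effect = nt$effect[idx],
                                   stringsAsFactors = FALSE))
      candidates <- present[present$effect == "missense", , drop = FALSE]
      if (nrow(candidates) < n_hits) {
        stop("library holds only ", nrow(candidates),
             " distinct missense changes; cannot plant ", n_hits,
             call. = FALSE)
      }
      pick <- candidates[sample.int(nrow(candidates), n_hits), , drop = FALSE]
      truth <- data.frame(codon_index = pick$codon_index,
                          alt_aa = pick$alt_aa,
                          delta_r = delta_r, stringsAsFactors = FALSE)
      truth <- truth[order(truth$codon_index, truth$alt_aa), , drop = FALSE]
      rownames(truth) <- NULL
    }
    fitness <- fitness_model(baseline_rate = 0, effects = truth)
    rates <- clone_growth_rates(library, space, fitness)
    traj <- simulate_selection(rates, schedule, mode = mode)

    counts <- list(
      library = simulate_counts(rep(1, library$n_inserts), library, cds,
                                seqmodel, sample_id = "plasmid_library")
    )
    for (k in seq_along(schedule$sampling_days)) {
      day <- schedule$sampling_days[k]
      counts[[paste0("day", day)]] <-
        simulate_counts(traj$abundance[, k], library, cds, seqmodel,
                        sample_id = paste0("day", day))
    }
    list(library = library, fitness = fitness, rates = rates,
         trajectories = traj, counts = counts, ground_truth = truth)
  })
  structure(c(list(cds = cds, space = space), sim),
            class = "screen_simulation")
}

#' @export
print.screen_simulation <- function(x, ...) {
  cat("<screen_simulation> ", x$library$n_inserts, " inserts, ",
      nrow(x$ground_truth), " planted activators, sampling days: ",
      paste(x$trajectories$sampling_days, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Ground-truth hit table of a simulated screen
#'
#' @param sim A [simulate_screen()] result.
#' @return Data frame `(codon_index, alt_aa, delta_r)` of planted activating
#'   changes; empty when the fitness model is all-neutral.
#' @export
ground_truth <- function(sim) {
  stopifnot(inherits(sim, "screen_simulation"))
  sim$ground_truth
}
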