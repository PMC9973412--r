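---
title: "Models and methods behind snvscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind snvscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snvscreen)
```

# The experiment this package models

A saturation mutagenesis screen asks which single-nucleotide variants of a
coding sequence confer a growth advantage on the cells that express them.
The wet-lab shape is: (1) error-prone PCR introduces random substitutions
into a cDNA insert; (2) the mutant library is expressed in a cell pool whose
survival depends on the encoded protein's activity (the classic background
is the IL3-dependent Ba/F3 line, deprived of IL3 so that only clones with an
activated receptor — here ligand-stimulated — keep proliferating); (3) the
insert is amplicon-sequenced very deeply from the plasmid library and from
the selected pool; (4) each variant's change in frequency identifies drivers
of clonal expansion. `snvscreen` implements the computational side of all
four stages, plus a generative model of the experiment with known ground
truth.

# Variant space

For a CDS of length $L$ every position admits 3 substitutions, giving $3L$
nucleotide variants. Each maps to a codon-level amino-acid change; distinct
changes are the deduplicated $(codon, alt\_aa)$ pairs. Two conventions are
worth stating because they drive the headline coverage numbers:

* **Stop handling.** The terminal stop codon is part of the mutagenized
  insert, so it is enumerated by default; its substitutions are classed
  `stop_altering` (or `synonymous` when the altered codon is still a stop),
  and neither class is counted in the "missense or nonsense" totals used as
  coverage denominators.
* **Effect partition.** `synonymous + missense + nonsense + stop_altering`
  always sums to $3L$; transitions are exactly $L$ and transversions $2L$
  for a full space, because each base has one transition and two
  transversion alternates.

## The per-insert coding-load convention

`expected_coding_changes_per_insert(rate, space)` multiplies a nucleotide
mutation rate by the ratio *distinct amino-acid-level missense+nonsense
changes / nucleotide-level space size* — e.g.
$2.59 \times 8{,}065/11{,}638 = 1.79$. This is a **reporting convention**,
not the expectation of a simulation: the realized number of
amino-acid-changing substitutions per insert is the rate thinned by the
*nucleotide-level* missense+nonsense fraction (about 0.75 rather than 0.69
for a typical CDS), because several nucleotide routes can reach the same
amino-acid change. The package keeps the convention for the headline
statistic — it is the arithmetic this field reports — and the test suite
checks the simulator against the nucleotide-level expectation it actually
realizes. Relatedly, $3 \times 3{,}879 = 11{,}637$; published figures
sometimes print 11,638 under an endpoint convention that is not
recoverable, so count-based coverage helpers accept the printed counts
as-is while `enumerate_snv_space()` always returns exactly $3L$ rows.

# The synthetic screen

`simulate_screen()` stacks four generative stages, each independently
seeded and testable.

**Mutagenesis.** Substitutions per insert are Poisson with mean 2.59 by
default (a realistic error-prone PCR load for a ~3.9 kb insert; 2.11 is a
typical sibling-library value). Positions are uniform; at most one variant
per position per insert (they are in cis on one molecule); the alternate
base is drawn from a 12-cell ordered-substitution spectrum conditioned on
the reference base, uniform unless specified.

**Fitness.** Selection acts at the clone (insert) level. An insert's net
growth rate is `baseline + combine(effects of its aa changes)`, with
`combine = max` by default: a single sufficiently activating change is
enough for survival, so a second driver on the same molecule adds nothing.
This is deliberate — it reproduces the central confound of real screens,
*passenger hitchhiking*: a neutral variant sharing an insert with a driver
enriches with it. The default baseline is 0/day (a pool that is static
without an activating variant) and the planted driver advantage is 0.6/day,
set a priori so that the day-8 enrichment $e^{8 \times 0.6} \approx 120$
lands mid-way inside the 57–464-fold band reported for genuine activating
variants in screens of this design.

**Pool complexity.** Real screens transduce millions of cells, putting each
possible variant on the order of $10^3$ independent inserts; hitchhikers
are then diluted by their many driver-free siblings and never rank with the
drivers. That scale is not desk-computable, so the default is 50,000
inserts — about 10 inserts per possible variant. This was chosen once, from
the dilution argument (a hitchhiker on one of $k$ inserts has expected fold
change $\approx (G + k - 1)/k$ for driver enrichment $G$, so $k \approx 10$
keeps it well under the 50-fold cutoff, and a single-copy hitchhiker —
which would tie a driver — has probability $\approx e^{-k}$ per
occurrence). A green end-to-end test therefore establishes that scoring
separates drivers from hitchhiker-diluted passengers at this complexity; it
does not establish performance at bottlenecked complexities (say, <3
inserts per variant), where ties between drivers and single-copy
hitchhikers are expected and the screen design itself (not the scoring)
is the limit.

**Selection.** Deterministic mode steps $a_i(t) = a_i(0)e^{r_i t}$ in whole
days; passaging rescales all clones equally, so relative frequencies are
exactly dilution-invariant (a property the tests pin). Stochastic mode
implements passaging as per-clone binomial thinning, the main genuine-drift
ingredient at these pool sizes.

**Sequencing.** At each locus, `depth` reads are drawn from one multinomial
over the four bases at the pool's true base frequencies, mixed with a
per-base error rate $\varepsilon$ (a miscalled read lands uniformly on the
three alternates): $p' = p(1-\varepsilon) + \frac{\varepsilon}{3}(1-p)$.
Per-locus counts sum to the depth by construction. Not modeled, and hence
not validated by any green test here: PCR jackpots/duplicates, read-level
alignment artifacts, strand bias, and in-cis phasing (amplicon reads are
too short to phase a multi-kb insert, which is also why scoring is
per-variant).

# Enrichment scoring

**Assessability.** A variant is scored only if observed in both the library
and the timepoint, with library reads at or above `min_library_reads`
(default 10 ≈ 3× the expected per-alternate error reads at the default
depth 10^5 and error 10^-4; scale it with `depth × error_rate / 3` for
other settings). This mirrors restricting the analysis to variants present
in the sequencing data of both samples, with "present" meaning above the
error floor.

**Fold change.** The frequency ratio, exactly, for variants observed in the
library. The pseudocount policy (default 0.5 reads added to both variant
counts) applies only to zero-library variants so their fold change is
finite; the `strict` policy returns `NA` for them instead. The exact-ratio
choice keeps the definitional identities — equal frequencies give exactly
1 — intact.

**Significance.** No particular test is canonical for these screens; the
package defaults to the exact conditional test of the 2×2 table
(variant/other × library/timepoint) because hit calling happens at
$q < 10^{-5}$, an extreme tail where normal approximations are exactly
where they fail. The two-sided p sums hypergeometric probabilities no more
likely than the observed table. The conditional support has only
`lib_reads + tp_reads + 1` points, so the exact test is fast even at
$10^5\times$ depth. A pooled two-proportion z (`test = "approx"`) is
available for very large variant counts; q-values are step-up
Benjamini–Hochberg across the assessable family, implemented in one place
and shared with the assay-statistics module.

**Thresholds.** Defaults `fold ≥ 50` and `q < 1e-5`; 47 is the natural
preset for a replicate screen scored the same way. Both are parameters of
`hit_call_params()`, and stricter settings provably call a subset of hits.

# Dose–response fitting

The four-parameter log-logistic model
$f(x) = c + \frac{d - c}{1 + \exp(b(\ln x - \ln e))}$ is fit by least
squares. Implementation choices that matter numerically:

* the asymptotes enter linearly given $(b, \ln e)$, so they are profiled
  out by a 2-column linear solve and the optimizer works on the
  well-scaled $(b, \ln e)$ plane, multistarted over an 8×5 grid of slopes
  and dose-quantile midpoints, then jointly refined;
* zero-dose controls anchor the untreated asymptote via the $x \to 0$
  limit and are excluded from the log-dose axis;
* the parameter covariance is computed from the fitted-value Jacobian on
  the $(b, c, d, \ln e)$ scale and mapped to the `ll4` ($e$-scale) or
  `ll2_4` ($\ln e$-scale) parametrization by the delta method — the direct
  $e$-scale crossproduct is numerically singular at nanomolar IC50s;
* non-convergence is an explicit state (`converged = FALSE`, `ic50 = NA`)
  with the failure reason, never a silently wrong number.

Both parametrizations give the same curve; tests pin IC50 agreement to
within $10^{-4}$ relative on well-conditioned data, exact recovery on
noiseless curves across a slope grid $b \in [0.5, 3]$, and 10% accuracy at
2% response noise. Five-parameter asymmetric models (display-fitting
territory) are out of scope.

Doubling times use the exponential closed form $t \ln 2 / \ln(N_t/N_0)$,
the standard reading of "time from seeding readout to saturation readout
under exponential growth"; it is scale-invariant in the readout. Group
comparisons are Welch two-sample *t* tests (Welch–Satterthwaite df) with BH
adjustment across the declared family; comparisons in which both arms have
zero variance are flagged and excluded rather than given a fake p-value.

# Degenerate inputs and tie-breaks

* CDS validation rejects non-multiple-of-3 lengths, any non-ACGT character
  (naming the position), a declared terminal stop that is not one, and
  internal stops.
* Count-table readers reject rather than repair: counts above totals,
  duplicate `(pos, alt)` rows, and inconsistent per-locus totals are hard
  errors with row numbers.
* All-equal fitness gives frequency trajectories identical to the initial
  vector (selection neutrality), pinned exactly in tests.
* BH ties: the step-up cummin construction makes q-values invariant to
  input permutation; ties in p give equal q.
* Exact-test two-sidedness uses the `(1 + 1e-7)` likelihood-comparison
  slack standard for hypergeometric equality in floating point.

# Known limitations

* Scoring is per-variant; in-cis co-operation between variants is neither
  simulated as an interaction nor detectable by the scoring (inserts are
  short-read sequenced in the modeled world too).
* The simulator samples counts directly; read-level artifacts (alignment,
  PCR duplication, strand bias) are out of its vocabulary, so robustness to
  them is untested by design.
* The exact test conditions on margins and treats reads as independent;
  overdispersion from clone sampling in a bottlenecked pool would make its
  p-values anti-conservative. At the default complexity and depth this is
  negligible (the neutral-null suite observes zero false hits at
  $q < 10^{-5}$ across 50 replicates), but a heavily bottlenecked screen
  should use replicate-level variance instead.
* Percentages are reported to one decimal; that is a formatting convention,
  not an accuracy claim.
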