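Package: snvscreen
Title: Saturation Mutagenesis Screens: Variant Spaces, Selection
    Simulation, and Enrichment Scoring
Version: 0.1.0
Authors@R:
    person("Screen", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cell-based saturation mutagenesis screens of a
    coding sequence. Enumerates and classifies the complete
    single-nucleotide substitution space of a CDS, computes library
    coverage and substitution-spectrum statistics, simulates error-prone
    PCR mutant libraries with clonal selection under per-variant fitness
    effects and multinomial deep sequencing, and scores per-variant
    enrichment (variant frequency, fold change versus the plasmid
    library, exact-test p-values with Benjamini-Hochberg FDR control,
    and threshold-based hit calling). Also includes the small assay
    statistics used around such screens: exponential doubling times,
    four-parameter log-logistic dose-response (IC50) fitting, and
    Welch t tests with FDR adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
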