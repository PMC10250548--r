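Package: nascentquant
Title: Quantitative Analysis of Metabolically Labeled Nascent Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-search analysis of metabolic-labeling proteomics
    experiments in which newly synthesized proteins carry a clickable
    threonine analog alongside stable-isotope markers. Provides
    incorporation-rate estimation from matched modified/heavy peptide
    pairs, newly-synthesized-protein calling with background-binder
    subtraction, left-censored (MinProb) imputation with an
    imputation-stability differential-enrichment wrapper built on an
    empirical-Bayes moderated t-test and Benjamini-Hochberg FDR,
    pulse-labeling time-course analytics (label specificity, presence
    dynamics, z-score profiles, per-protein ANOVA), amino-acid
    composition and modification mass-delta utilities, and a
    synthetic-data generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
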