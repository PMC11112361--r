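Package: kinact
Title: Kinome Activity Profiling from Targeted T-Loop Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies kinase activity from targeted mass-spectrometry
    measurements of kinase activation-loop (T-loop) phosphopeptides with
    stable-isotope-labeled internal standards. Implements transition-level
    interference filtering (signal-to-noise, light/heavy relative-contribution
    mismatch, sparsity, ratio-consistency transition selection),
    internal-standard-normalized log2 abundance estimation with oxidation
    collapsing, differential-activity statistics across treatment-outcome
    groups (t-test, one-way ANOVA with Tukey HSD, Pearson correlation,
    hierarchical clustering), ROC/AUC analysis and rule-based multi-kinase
    predictive panels fitted by multiple logistic regression, plus a
    synthetic-cohort generator with a ground-truth ledger for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
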