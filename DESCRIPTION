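Package: uromir
Title: Qualification of Urinary miRNA Diagnostic Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for qualifying urinary microRNA
    diagnostic biomarkers from case-control qPCR studies. Provides synthetic
    cohort generation with a known ground truth, propensity-score
    nearest-neighbor caliper matching on age and sex with covariate-balance
    diagnostics, replicate aggregation and global-mean selection of internal
    control assays, 2^-deltaCt relative quantification, fold-change plus
    Mann-Whitney discovery screening, and diagnostic evaluation via ROC/AUC,
    Youden-index cutoffs, stratified k-fold cross-validation and percentile
    bootstrap confidence intervals. An end-to-end pipeline reproduces the
    full study design from cohort assembly through per-marker qualification
    reports.
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
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
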