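Package: mrpath
Title: Two-Sample Mendelian Randomization with Mediation, Meta-Analysis
    and Omics Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for summary-statistics Mendelian randomization (MR)
    along the diet-microbiota-metabolite-disease axis: instrument
    selection and quality control (p-value tiers, greedy LD clumping,
    variance explained, F-statistics, confounder screening), allele
    harmonization with palindromic-SNP handling, an estimator battery
    (IVW, weighted median, mode-based, MR-Egger) with sensitivity
    analyses (Cochran's Q, Egger intercept, MR-PRESSO), two-step
    mediation decomposition with proportion-mediated intervals,
    random-effects meta-analysis of odds ratios from printed confidence
    intervals, and permutation Mantel tests plus BH-corrected
    correlation networks for microbiome-metabolome integration. Seeded
    synthetic-data generators with known causal structure make every
    stage testable without external GWAS downloads.
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
    vegan,
    withr,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
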