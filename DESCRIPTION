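Package: lipidmr
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) analyses of
    GWAS summary statistics, built around the design of large lipid
    biomarker-to-disease studies. Covers reading, validation and
    effect-allele harmonization of summary tables; genetic-instrument
    construction by genome-wide significance filtering, greedy LD clumping,
    cross-trait pruning and heterogeneity-driven pruning; single-exposure MR
    estimators (inverse-variance weighted under fixed or multiplicative
    random effects, MR-Egger, weighted median, mode-based) with Cochran's Q,
    Egger-intercept, Steiger directionality and analytic power diagnostics;
    multivariable MR with conditional instrument-strength statistics and
    invalidity pruning; locus-restricted MR on conditionally independent
    variants with fixed-effects meta-analysis across loci and per-SNP
    meta-analysis of two GWAS; cross-trait LD-score regression with
    block-jackknife uncertainty; and a seeded generator of two-sample GWAS
    summary statistics and LD-score panels with known ground truth, so that
    every stage can be verified by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    MASS,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr
Config/testthat/edition: 3
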