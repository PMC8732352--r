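Package: mbcrs
Title: Methylation-Based Breast Cancer Risk Scores from Case-Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derivation and validation of blood DNA-methylation breast cancer
    risk scores from case-cohort studies. Provides a synthetic case-cohort
    generator with known ground truth, sample-level quality control for
    450K-style beta-value matrices, linear DNAm estimator computation and
    epigenetic age-acceleration residuals, age-balancing inverse-probability
    selection weights and Barlow case-cohort weights, an observation-weighted
    elastic-net Cox solver with pathwise coordinate descent and cross-validated
    penalty selection, and the full validation toolkit: Barlow-weighted Cox
    association models with robust variance on the age timescale, standardized
    covariate-adjusted residuals, odds ratios per adjusted standard deviation
    (OPERA), and DeLong-based sequential AUC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    data.table,
    jsonlite,
    nnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
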