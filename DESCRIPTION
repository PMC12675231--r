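Package: phenospline
Title: Metabolic Obesity Phenotyping and Spline-Based Biomarker Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis pipeline linking a plasma biomarker
    (oxytocin) and an adiposity signal (leptin) to disordered-eating
    severity across metabolic obesity phenotypes. Provides a seeded
    synthetic cohort generator, derived metabolic indices (HOMA-IR,
    hepatic steatosis index, visceral adiposity index) with four-group
    phenotype classification, nonparametric group comparisons
    (Kruskal-Wallis, Dunn's post hoc test with tie correction, false
    discovery rate control, Spearman matrices), OLS with HC3 robust
    inference and backward elimination, restricted-cubic-spline logistic
    dose-response curves with bootstrap bands, leakage-free nested
    cross-validation with elastic-net tuning, out-of-fold discrimination
    and calibration metrics, Youden-index threshold discovery inverted to
    the biomarker scale with bootstrap confidence intervals, paired
    bootstrap AUC comparison, and decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    sandwich,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    car,
    withr,
    optparse
Config/testthat/edition: 3
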