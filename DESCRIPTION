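Package: adaptms
Title: Adaptive Per-Sample Classification of Discovery Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagnostic classification of individual discovery-proteomics
    samples without test-side imputation. A relaxed candidate feature list is
    built from a discovery cohort by repeated stratified subsampling with
    Welch t-tests under FDR control; for every test sample a ridge-penalized
    logistic model is refit de novo on the intersection of that list with the
    proteins the sample actually quantified, so predictions use only measured
    values. Includes one-vs-rest multiclass classification, retrospective
    covariate-matched cohort assembly from a proteome database, fixed-feature
    random-forest/gradient-boosting and non-refit baselines, a synthetic
    cohort generator with abundance-dependent (missing-not-at-random)
    dropout and multi-site batch effects, and an evaluation harness with
    repeated stratified cross-validation, learning curves, cross-site
    evaluation and per-sample feature-usage diagnostics.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
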