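Package: gsnue
Title: Genomic Selection Model Comparison for Nitrogen Use Efficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for comparing genomic selection (GS) models on
    nitrogen use efficiency (NUE) in bread wheat and similar quantitative
    traits. Implements nine GS predictors (rrBLUP, gBLUP, LASSO, Bayesian
    ridge, RKHS kernel regression, support vector regression, gradient
    boosting, bagging and stacking) from their mixed-model-equation and
    regularized-objective forms, together with the surrounding evaluation
    machinery: marker quality control, genomic relationship and Gaussian
    kernel matrices, spectral REML variance components and SNP heritability,
    nested cross-validation, bootstrap GEBV summaries, a learning-rate
    schedule, KNN-based bias-variance decomposition, adaptive standard error
    of prediction for pairwise model comparison under FDR control, and
    expected genetic selection gain with relative efficiency. Ships a
    synthetic wheat-like population generator (subpopulation structure, LD
    blocks, additive QTL architecture, two nitrogen environments at target
    heritabilities) so the whole pipeline runs and is testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR
Suggests:
    glmnet,
    kernlab,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
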