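Package: equibench
Title: Benchmarking Multiethnic Machine Learning Disparities with Transfer Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates two-group labelled omics cohorts with controllable data
    inequality (unequal group sizes) and distribution discrepancy (differentially
    expressed features and group-specific logistic feature effects), and benchmarks
    three multiethnic machine learning schemes on them: mixture learning (one model
    for the pooled cohort), independent learning (one model per group), and transfer
    learning from the data-rich to the data-poor group (back-propagation fine-tuning,
    stacked denoising autoencoder pretraining, and contrastive classification
    semantic alignment domain adaptation). Provides stratified threefold
    cross-validation, AUROC evaluation, and disparity-gap reports, plus estimation
    of the generator's parameters from a real cohort via permutation t-tests and
    per-group logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
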