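Package: gnetox
Title: Random Neural Network Classifiers for QSAR Bioactivity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative structure-activity relationship (QSAR) modelling of in
    vitro bioactivity with G-Network / Random Neural Network (RNN) classifiers.
    Provides the G-Network product-form steady state via fixed-point iteration, a
    discrete-event simulator of the underlying Markov chain, recurrent
    gradient-descent learning, a multi-layer RNN (MLRNN) with a fixed random
    projection and ridge least-squares readout, from-scratch SMOTE minority
    oversampling, an assay-matrix curation pipeline (complete-submatrix
    extraction, AC50 binarization, prevalence filters, descriptor
    normalization), a repeated random-split benchmark harness reporting
    sensitivity, specificity and balanced accuracy, and a seeded generator of
    ToxCast-like synthetic fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
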