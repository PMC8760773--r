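Package: hslda
Title: Hierarchical Supervised Topic Models for Clinical Risk Stratification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a four-layer hierarchical supervised latent Dirichlet
    allocation (sLDA) model to bags of clinical feature-value pairs, such as
    coded hospital discharge records. Topics generate a clinical feature and
    then a value within that feature's block, and a softmax generalized
    linear model over empirical topic frequencies generates a diagnosis
    class. Provides mean-field variational Bayes EM inference with an exact
    small-instance evidence oracle, class prediction, topic-based risk
    stratification tables, TF-IDF token weighting, SMOTE class balancing,
    stratified cross-validation with macro-averaged metrics, a generative
    simulator for end-to-end testing, and a flat (single-feature) reduction
    equivalent to multi-class sLDA.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
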