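Package: neurosym
Title: Mental-Health Symptom Classification from Task EEG Source Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for predicting binary mental-health
    symptom labels (anxiety, depression, inattention, hyperactivity) from
    per-subject tensors of source-localized EEG spectral amplitudes
    (68 Desikan-Killiany regions x 3 frequency bands x 5 cognitive tasks).
    Provides interaction-feature augmentation (statistical summaries,
    pairwise products and calibrated log transforms), feature selection by a
    continuous extension of the chi-squared statistic, SMOTE and
    Gaussian-noise oversampling, stratified cross-validated L2-regularized
    logistic regression with permutation-null controls, and identification
    of "hub" region pairs via chi-square strength aggregation and
    current-flow closeness/betweenness centralities. Includes a synthetic
    cohort generator with planted main and cross-region interaction effects
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    MASS,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
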