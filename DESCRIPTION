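Package: ConnStab
Title: Stability of Sparse Classifiers for Functional Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares elastic-net-regularized and AIC-stepwise logistic
    regression for detecting impaired resting-state functional connectivity
    in Alzheimer's disease. Provides the full pipeline: Fisher-z pairwise
    connectivity featurization of ROI time series (nuisance regression,
    ideal band-pass filtering, Pearson correlation), an elastic-net
    coordinate-descent solver and a bidirectional AIC-stepwise search for
    binary diagnosis, repeated stratified subsample validation with
    held-out AUC, feature-selection-frequency and consensus-network
    analysis, variance inflation diagnostics, demographic group
    comparisons, and a multi-site synthetic cohort generator with stored
    ground truth for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
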