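Package: exalert
Title: Exacerbation Early Warning from Home Urine-Biomarker Telemonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an early-warning system for
    COPD exacerbations from daily home urine-biomarker tests. Includes a
    synthetic longitudinal cohort generator; paired stable/exacerbation
    biomarker screening with AUC and t-test selection rules and backward
    stepwise logistic panel fitting; a Bayesian non-homogeneous dynamic
    linear model per biomarker (level drift, AR(1) day-to-day fluctuation,
    device-batch step changes, observation noise) fitted by Gibbs sampling
    with forward-filtering backward-sampling and missing-data augmentation,
    together with a strictly causal Kalman filter; rolling-window temporal
    feature extraction with time-to-exacerbation labels; stepwise
    neural-network input selection under Monte Carlo 60:20:20
    cross-validation producing a "time to exacerbation" risk score; and
    traffic-light decision rules with event-level predictive-value
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
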