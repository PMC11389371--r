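Package: micropolate
Title: Interpolation and Accuracy Prediction for Longitudinal Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for interpolating missing samples in longitudinal
    compositional microbiome time series and for studying what drives
    interpolation accuracy. Implements a roster of interpolation methods
    (naive mean/median/last, uniform null, weighted average,
    Epanechnikov-kernel K-nearest-neighbours, cubic spline, discretized
    generalized Lotka-Volterra models with least-squares, ridge (MLRR) and
    sparse bootstrap (LIMITS) estimators, and linear-Gaussian dynamic
    Bayesian networks), a leave-one-out evaluation framework scored with
    Bray-Curtis similarity, community- and taxon-level stability
    diagnostics (time-point stability, bimodality coefficient), Monte-Carlo
    sample-size and sampling-frequency experiments, a mixed-effects model
    that predicts per-sample interpolation accuracy, and a seeded synthetic
    cohort generator with adult-like stable and infant-like successional
    dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    lme4,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    e1071,
    optparse,
    biomformat
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
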