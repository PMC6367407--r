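Package: funrf
Title: Functional Random Forests for Dose-Response Curve Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble regression trees whose node deviances and leaf
    predictions operate on entire dose-response curves rather than scalar
    summary metrics. Node costs include region-wise sums of squared
    deviances, principal-component and basis-coefficient deviances,
    Mahalanobis (multivariate) deviance, and f-divergences (Kullback-Leibler,
    Hellinger) between per-dose response distributions. Leaves store whole
    curves; predictions are formed dose-wise from the forest-weighted
    response distribution. Includes B-spline and four-parameter logistic
    curve fitting, drug-sensitivity summary metrics (AUC, IC50, EC50, Amax,
    IC percentiles), function-to-function feature extraction from
    dose-expression curves, a frequency-based variable importance measure, a
    synthetic sigmoid benchmark generator, and cross-validation and
    bootstrap model-comparison drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    randomForest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
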