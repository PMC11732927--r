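Package: edcast
Title: Early-Warning Forecasting of Mortality-Associated Emergency Department Crowding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates and analyses hourly sectioned emergency department (ED)
    occupancy panels, labels mortality-associated crowding days (occupancy
    ratio at or above 90% of bed capacity for three or more hours in a
    calendar day), assembles a leak-free multi-origin design matrix with
    week-long hourly lookback features, trains a gradient-boosted tree
    classifier under a daily expanding-window retraining protocol, and
    evaluates it with a full binary-metric panel, percentile-bootstrap
    confidence intervals, and Shapley / local-surrogate feature attribution.
    Includes a calibrated nonhomogeneous Poisson arrival queue simulator so
    the whole pipeline is testable without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    data.table,
    xgboost,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'attribution.R'
    'crowding.R'
    'features.R'
    'forecast.R'
    'io.R'
    'metrics.R'
    'pipeline.R'
    'simulate.R'
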