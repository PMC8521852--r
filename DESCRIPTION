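Package: wearday
Title: Day-Type Clustering and Usage Analytics for Hearing Aid Data Logging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for analysing longitudinal, hour-resolved
    hearing aid usage logs. Raw per-ear logs are resolved binaurally, use
    during temporary Bluetooth disconnections is imputed from on-device time
    counters, and days are filtered to a clean day-by-hour wear-time matrix.
    The package computes amount-of-use statistics (between- and within-user
    variability, light/medium/heavy segments, a quadratic variability curve),
    discovers typical day-of-use patterns by k-means++ clustering with elbow
    and silhouette diagnostics, segments users on their day-type proportions
    with four clustering techniques scored by internal validation metrics
    (including a hierarchical density-based method that marks noise users),
    and validates the user segmentation with a majority-vote ensemble of
    three supervised classifiers. A synthetic cohort generator with known
    ground truth makes every stage testable without access to proprietary
    logging data.
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
    nnet,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
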