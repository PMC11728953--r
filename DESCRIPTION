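Package: rdkidney
Title: Predicting Rapid Decline of Kidney Function in Type 2 Diabetes
    from Longitudinal Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for predicting rapid decline (RD) of kidney
    function among type-2 diabetes patients from irregular longitudinal
    laboratory records. Labels every eGFR test date as RD or not via
    LOWESS-smoothed trajectories (smoothed eGFR below 60 mL/min/1.73m2 with a
    drop of 5 or more versus one year earlier), constructs eligible decision
    points with one-year event-window outcomes, engineers 2-week "space"
    features over a 54-week input window (nearest-neighbour daily
    interpolation, log-of-mean representatives, missingness preserved), trains
    a leaf-wise gradient-boosted tree classifier with recursive feature
    elimination and patient-grouped cross-validation, and evaluates with a
    patient-level holdout, bootstrap confidence intervals, variance inflation
    factors and cohort-characteristics tests. A synthetic electronic health
    record generator with planted decline episodes makes every stage testable
    without protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
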