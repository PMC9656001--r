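Package: odit
Title: Online Discrepancy Test for Sequential Multivariate Anomaly Detection and Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric sequential (online) detection of persistent anomalies in
    multivariate data streams using k-nearest-neighbor distances to an estimated
    minimum-volume set of nominal training data, with a CUSUM-like accumulation of
    anomaly evidence. Includes per-dimension anomaly localization via one-sided
    t-tests on kNN distance contributions, an approximate nearest-neighbor backend
    based on a priority-search k-means tree, threshold calibration against a false
    alarm constraint, and a simulation harness for change-in-mean and
    change-in-correlation experiments (average detection delay versus false alarm
    rate, detection and localization ROC analysis).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
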