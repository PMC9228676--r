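Package: plankcascade
Title: Plank Technique Classification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies plank (prone bridge) exercise technique from
    body-worn inertial measurement units. Reduces five-sensor, 60-channel
    IMU recordings to stable-window features, engineers cross-sensor
    maximum features, and classifies an acceptable plank against six named
    technique deviations with a binary-tree cascade: a univariate threshold
    node for the perfectly separable deviation, then at each node an
    empirical-tail aberrance filter followed by a binary random forest.
    Includes a synthetic IMU trial generator with subject random effects
    and an extreme-deviation mixture, a repeated stratified hold-out
    evaluation protocol with per-node confusion metrics, and Gini
    variable-importance reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
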