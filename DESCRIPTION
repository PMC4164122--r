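Package: pulmodpm
Title: Anatomic Pulmonary Gas-Exchange and Exercise Physiology Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Breath-by-breath simulation of respiratory gas exchange in an
    anatomic multi-compartment lung with gravity-dependent heterogeneous
    ventilation and perfusion, serial capillary gas uptake, and allometric
    species scaling (human, sheep, goat). Lung injury by fluid infiltration
    (edema) is represented as a paired reduction in oxygen diffusing capacity
    and a pulmonary shunt, calibrated from lung-weight-change data. A
    ventilatory-control and metabolic layer closes the loop and predicts
    physiologic responses to hypoxia, altitude and exercise, and an
    oxygen-deficit fatigue model predicts time to fatigue under damage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
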