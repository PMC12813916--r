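Package: myowork
Title: Noninvasive Myocardial Work Indices from Pressure-Strain Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for noninvasive myocardial work analysis from global
    longitudinal strain, brachial systolic blood pressure and cardiac valve
    event timings. Constructs a continuous left-ventricular pressure surrogate
    from valve-event-anchored templates, computes the four myocardial work
    indices (global work index, constructive and wasted work, work
    efficiency), time-normalizes pressure-strain loops and compares their
    shape between groups with dynamic time warping and Procrustes distances
    under label permutation, and provides population reference intervals and
    observer-agreement statistics (Bland-Altman, intraclass correlation).
    Includes a calibrated synthetic cohort generator so the full pipeline is
    testable without access to restricted population data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
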