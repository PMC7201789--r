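Package: apsafe
Title: Closed-Loop Artificial Pancreas Simulation with Dynamic
    Insulin-on-Board Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Desk-scale closed-loop simulator for a hybrid artificial
    pancreas control stack for type 1 diabetes: a proportional-derivative
    glucose controller with insulin feedback, a sliding-mode
    reference-conditioning safety layer (SAFE) that keeps estimated
    insulin-on-board (IOB) below a constraint, and a dynamic rule-based
    (DRB) tuner that derives a time-varying IOB limit from the patient's
    basal profile during fasting and raises it transiently after announced
    meals. Includes a surrogate minimal-model virtual-patient cohort with
    circadian insulin-sensitivity variation and per-meal absorption
    perturbations, a scenario engine with paired treatment arms, and
    standard continuous-glucose-monitoring outcome metrics (time in
    ranges, hypoglycemic events, glycemic excursion, GMI, CVGA zones).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
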