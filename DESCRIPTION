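Package: mscourse
Title: Conformal Prediction of Multiple Sclerosis Disease Course from
    Longitudinal Visit Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mondrian inductive conformal prediction for per-visit
    classification of multiple sclerosis disease course (relapsing-remitting
    versus secondary progressive) from longitudinal electronic health record
    style visit data. Provides a registry-like synthetic cohort simulator
    with known ground truth, the cleaning/carry-forward/derivation feature
    pipeline, probabilistic classifier wrappers, class-conditional conformal
    calibration with validity and efficiency evaluation, per-patient disease
    course trajectories with transition-time estimation, and additive
    per-visit feature attributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    e1071,
    xgboost,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
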