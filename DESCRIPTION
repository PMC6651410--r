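Package: comcop
Title: COM-COP Inclination Angle Estimation from a Waist-Mounted Inertial Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate the center of mass - center of pressure (COM-COP)
    inclination angle during walking from the nine channels of a single
    waist-mounted inertial measurement unit. Includes a physically consistent
    synthetic gait generator (whole-body COM, per-plate vertical ground
    reaction force and center of pressure, and IMU signals derived from one
    underlying motion), the biomechanical ground-truth computation of the
    inclination angle with gait-cycle segmentation and 100-frame time
    normalization, zero-phase Butterworth preprocessing, two seeded neural
    estimators (a frame-wise feed-forward network and a sequence-to-sequence
    LSTM), and subject-wise cross-validated evaluation with correlation,
    RMSE, relative RMSE and one-way ANOVA summaries.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
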