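Package: lumbarstretch
Title: Tri-Axial Lumbar Angle Estimation from Wearable Sheet Stretch Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates tri-axial lumbar motion angles (flexion-extension,
    side-bending, axial rotation) from four wearable sheet stretch sensors via
    crosstalk-adjusted linear combinations of the channel displacements and a
    short-window linear calibration against marker-based reference kinematics.
    Includes the optical reference pipeline (pelvis and trunk anatomical frames,
    Cardan X-Y-Z decomposition), zero-phase Butterworth preprocessing, agreement
    statistics (range of motion, RMS error, Pearson correlation, error ratio,
    Bland-Altman limits of agreement), and a trial-structured simulator of trunk
    movements, marker trajectories and sensor outputs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
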