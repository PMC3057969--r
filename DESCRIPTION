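Package: pointkin
Title: Kinematics and Endpoint-Variability Analysis of Communicative Pointing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for repeated 3D pointing gestures recorded with
    an active-marker motion-capture system. Smooths fingertip trajectories with
    an exponential filter, segments movements by a relative tangential-velocity
    threshold, extracts temporal parameters (corrected reaction time, duration,
    time to peak velocity, peak and mean velocity, distance), resamples
    trajectories to a fixed number of time-normalized points with
    repeated-measures ANOVAs per point, summarises 2D endpoint scatter as
    eigenvalue-normalized tolerance ellipses after Cook's-distance outlier
    exclusion, and tests differences in average-ellipse axial orientation
    between conditions with a within-subject Monte-Carlo resampling test.
    Includes a synthetic-experiment generator with known ground truth
    (minimum-jerk reaches, condition-dependent anisotropic endpoint scatter,
    balanced block design) for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
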