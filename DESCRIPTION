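Package: progaze
Title: Adaptive Gaze Tracking with Progressive Calibration for Remote Video Eye Trackers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a remote video eye-tracking
    pipeline with progressive (interaction-driven) calibration: markerless
    pupil and eye-corner feature extraction from grayscale eye-camera frames,
    polynomial regression from a 4D eye-feature vector to on-screen gaze
    coordinates with online sample appending, a dwell-based gaze interaction
    state machine with adaptive landing zones that doubles as a calibration
    source, patient-table motion estimation from masked dense optical flow,
    and a stepwise regression/prediction/fixed-model evaluation protocol.
    A synthetic-data module generates ground-truth gaze sessions, rendered
    eye frames and table videos so the whole stack is testable without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
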