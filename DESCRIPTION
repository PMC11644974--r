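Package: imuposture
Title: Infant Body Position Classification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying infant static body position
    (Supine, Prone, Sitting, Hands and Knees, Upright) from tri-axial
    accelerometer, gyroscope and magnetometer recordings made during
    naturalistic infant-caregiver play. Covers preprocessing (spline gap
    filling, polyphase 40 to 60 Hz resampling, low-variance artefact masking,
    zero-phase low/high-pass decomposition, roll and pitch estimation,
    clap-based audio-video synchronisation), sliding-window segmentation with a
    majority-label consistency rule, five hand-crafted feature groups
    (statistical, frequency, summary, difference, correlation), infant-grouped
    cross-validated random-forest and gradient-boosted classifiers, and
    feature-importance analyses (group ablation, absolute SHAP aggregation,
    sensor-subset comparison with Friedman tests and FDR correction). A
    synthetic session simulator generates labelled recordings with the same
    statistical structure so every stage can be exercised without access to
    infant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    grDevices,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
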