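Package: gaitphase
Title: Two-Sensor Inertial Gait Analysis via Denavit-Hartenberg Kinematics
    and Hip-Knee Phase-Difference Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes a pair of body-worn inertial orientation streams
    (thigh and shin sensors reporting unit quaternions) into three-dimensional
    hip and knee joint angles through a six-link Denavit-Hartenberg kinematic
    chain with closed-form inverse kinematics, and characterises gait by the
    phase-difference angles between hip and knee oscillations in the sagittal,
    frontal and transverse planes. Includes a spectral gait-frequency
    estimator, analytic-signal and cross-correlation time-lag estimators,
    normalized gait phase diagrams, a heuristic normal/hemiplegic gait
    classifier, and a synthetic two-sensor gait simulator with an IMU noise
    model for parameter-recovery testing. Readers and writers for the sensor
    and joint-angle CSV dialects and JSON phase reports are provided, together
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
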