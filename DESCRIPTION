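Package: fallsense
Title: Energy-Efficient Wearable Fall Detection: Duty-Cycled IMU Sensing
    Simulation and a CNN-LSTM Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying an interrupt-driven, energy-efficient fall
    detection workflow built around a waist-worn six-axis inertial
    measurement unit (IMU). Provides a sample-accurate simulator of the
    free-fall / motion / zero-motion interrupt registers and the
    finite-state transmission scheduler of an MPU6050-class sensor with a
    FIFO buffer; a labelled synthetic IMU trace generator covering eight
    activity classes (including four-phase falls); the server-side
    conditioning chain (axis remapping, decimation, range normalization,
    moving-average filtering, sliding-window assembly); a declarative
    CNN-LSTM fall-detection network with a framework-independent shape and
    parameter auditor plus a self-contained training engine (Adam,
    dropout, backpropagation through time); and confusion-matrix metrics
    (accuracy, fall sensitivity and specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
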