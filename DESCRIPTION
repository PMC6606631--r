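Package: normgait
Title: Virtual Normative Databases for Lower-Limb Sagittal Gait Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts hip, knee and ankle sagittal joint-angle waveforms over
    the gait cycle from walking speed, age, sex and body mass index.
    Waveforms are discretised into clinically meaningful key-points
    (extrema and event-anchored angles), one robust multilinear regression
    (stepwise predictor selection followed by iteratively reweighted least
    squares with bisquare weights) is fitted per key-point parameter, and
    continuous waveforms are rebuilt by piecewise quintic-spline
    interpolation. Includes a published coefficient table, leave-one-out
    cross validation, predictor-contribution sweeps with clinical
    significance thresholds, and a synthetic-population generator for
    end-to-end testing without motion-capture data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
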