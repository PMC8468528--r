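Package: dmama
Title: Dynamic Mean Ankle Moment Arm Analysis from Prosthesis-Embedded Load Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the dynamic mean ankle moment arm (DMAMA) of each stance
    phase from a six-axis load cell embedded in a prosthetic pylon, using
    quasi-static joint-moment transport and impulse ratios on nonuniformly
    sampled data. Includes load-cell-to-shank frame calibration by
    rotation-vector averaging, gait-event detection and stride segmentation,
    locomotion-mode classification from load-cell channels with linear
    discriminant analysis (forward feature selection and pre-toe-off window
    optimization), mixed-effects-style sensitivity regressions of DMAMA on
    prosthesis forefoot stiffness and ground incline, and a synthetic
    gait-session generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    stats,
    tools
Suggests:
    lme4,
    lmerTest,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
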