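Package: coxval
Title: External Validation of Published Cox Proportional Hazards Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for externally validating a published Cox proportional
    hazards prognostic model on an independent patient-level dataset.
    Reconstructs the prognostic index from published coefficients, assesses
    discrimination (Harrell's c, Gonen-Heller K, the D statistic and the
    explained-variation measures R2_D and R2_PM), checks fit via the
    calibration slope, an offset-constrained misspecification test and a
    proportional-hazards check, and assesses calibration through risk-group
    observed-versus-predicted survival using a transportable
    fractional-polynomial approximation to the baseline survival function.
    Includes a simulation module that generates derivation/validation pairs
    with known proportional-hazards structure and controllable
    miscalibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    foreign,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
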