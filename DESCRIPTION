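Package: endurofit
Title: Power-Duration Modelling for Endurance Performance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits and compares the two classical models of the power-duration
    relationship in endurance sport: the hyperbolic (critical-power) model and
    the power-law (Riegel) model. Provides closed-form curves and inverses in
    power, work and duration coordinates, linearised least-squares estimation,
    a fixed-fatigue-factor race-time calibrator, rate-of-exertion and fatigue
    accumulation for arbitrary piecewise-constant intensity profiles, fatigued
    power-duration curves, even and two-phase pacing analysis, duration-binned
    model-comparison statistics with an out-of-sample protocol, and seeded
    generators of synthetic athlete populations with contamination for testing
    the full pipeline. Includes personal-record case-study fixtures for two
    elite marathon runners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
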