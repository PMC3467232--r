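Package: srtbind
Title: Response Binding and Trial-by-Trial Dynamics in Serial Reaction Time Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-day bimanual serial reaction time
    (SRT) experiments. Provides a synthetic multi-day cohort generator that
    emulates the canonical task structure (32-item sequence, adaptive response
    windows, probe blocks), sequence-specific learning metrics with
    linear/quadratic learning-rate model selection, the error response
    function for post-error slowing, an autocorrelation-based estimator of
    motor chunk size with a cross-subject random-probe null, an AR(1)
    response-binding simulator with its closed-form autocorrelation oracle,
    and a linear dynamical system of trial-by-trial response preparedness
    fitted by expectation-maximization with exact Kalman smoothing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
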