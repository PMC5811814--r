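Package: adamsim
Title: Adaptive Anchoring Simulations of Judgmental Forecasting and Averaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Agent-based simulation of one-shot judgmental forecasting and
    average estimation from monetary time series. Implements the adaptive
    anchoring model (ADAM), in which a behavioral response is the product of
    an exponential stimulus-task similarity weight, an experience-dependent
    anchor (series mean under static presentation, last value under dynamic
    presentation), and multiplicative Gaussian perceptual noise. Provides the
    linear-trend and stationary stimulus series generators, baseline
    comparator forecasters (noisy regression next value, AR(1) by conditional
    least squares, simple exponential smoothing), a seeded factorial
    simulation of the 3 presentation-mode x 3 trend-direction x 2
    trend-consistency design for both judgment tasks, and the statistical
    harness (pooled t tests with effect size r, Levene's test, SD-ratio
    diagnostics, epsilon-squared factorial ANOVA, split-half cross-validation)
    used to compare models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
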