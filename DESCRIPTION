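Package: walkmet
Title: Nonlinear Estimation of Submaximal Effort Tolerance (METs) from the
    Six-Minute Walk Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and tools for estimating the MET score of a submaximal
    treadmill exercise test from six-minute walk test (6MWT) distance or
    average walk velocity in pulmonary rehabilitation cohorts. Implements a
    staged treadmill-protocol distance/velocity framework (modified Bruce
    preset), a polynomial MET-velocity model with the resting intercept
    fixed at 1 MET, a continuous piecewise-linear MET model whose change
    points are located by a combined least-squares/genetic-algorithm
    search, leave-one-out cross-validation, rehabilitation group
    assignment from MET thresholds or model-derived switch points, a
    synthetic COPD cohort generator for parameter-recovery experiments,
    and plain-text cohort readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
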