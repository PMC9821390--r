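Package: histest
Title: Frequentist Inference and Study Design with Historical Parameter Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Principled frequentist inference when some model parameters are
    fixed at, or pooled with, previously published ("historical") estimates.
    Implements three estimators -- a Type-I plug-in estimator, a Type-II
    two-step estimator with precision-weighted (GLS) pooling of nuisance
    parameters, and a summary-combination estimator for coarsened data --
    together with their asymptotic covariance matrices, Loewner-order
    efficiency comparisons, and two design applications: optimal allocation
    for a 2x2 factorial combination trial with historical single-treatment
    studies, and greedy optimal allocation for Bliss-independence drug
    interaction studies. Includes seeded data generators and a Monte Carlo
    harness that validates the asymptotic formulas empirically.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
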