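Package: ierdjpc
Title: Inference for the Inverted Exponentiated Rayleigh Distribution under
    Joint Progressive Type-II Censoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Likelihood and Bayesian inference for two lifetime samples that
    follow inverted exponentiated Rayleigh distributions with a common scale
    parameter, observed under a joint progressive type-II censoring scheme.
    Provides the distribution functions, a simulator for the joint censoring
    mechanism, maximum likelihood estimation via an expectation-maximization
    algorithm with an independent direct optimizer as cross-check, the
    observed Fisher information matrix by the missing-information principle,
    parametric Bootstrap-p and Bootstrap-t confidence intervals,
    importance-sampling Bayesian estimation under squared-error and linex
    loss with weighted credible intervals, Kolmogorov-Smirnov and
    likelihood-ratio model checks for complete samples, and a Monte Carlo
    study driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
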