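Package: vkfilter
Title: Volatile Kalman Filtering for Learning in Changing Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling learning under volatility. Implements the
    volatile Kalman filter (VKF), a Bayesian error-correcting learner that
    tracks both a latent mean and the time-varying process variance
    (volatility) driving it, for Gaussian and binary observations; the
    classical Kalman filter and Rescorla-Wagner rule as special cases and
    comparators; two- and three-level hierarchical Gaussian filters (HGF)
    with detection of their numerical failures; near-exact sequential Monte
    Carlo benchmarks (bootstrap and Rao-Blackwellized particle filters);
    generative samplers for the volatility process, the HGF cascade and
    switching probabilistic tasks; and response models with MAP and
    empirical-Bayes hierarchical fitting, parameter-recovery and
    change-point analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
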