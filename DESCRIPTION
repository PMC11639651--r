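Package: postDCA
Title: Bayesian Decision Curve Analysis for Binary and Survival Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian estimation and interrogation of decision curves for
    clinical prediction models and diagnostic or prognostic tests. Net
    benefit posteriors are obtained in closed form for binary outcomes via
    a conjugate Beta-Bernoulli model of prevalence, sensitivity and
    specificity, and for survival outcomes via a Bernoulli positivity
    model combined with a right-censored Weibull time-to-event model
    sampled by MCMC. Posterior decision curves can be interrogated for the
    probability that a strategy is clinically useful, the probability that
    it is the best strategy available, pairwise superiority with a
    tolerance margin, and the expected value of perfect information
    (EVPI). Includes synthetic-data generators for logistic and Weibull
    proportional-hazards populations and a simulation harness measuring
    interval coverage and estimation error against population oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    rjags,
    coda,
    ggplot2,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse
Config/testthat/edition: 3
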