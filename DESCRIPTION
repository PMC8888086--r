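Package: pmlindley
Title: The Power-Modified Lindley Distribution: Inference and Stress-Strength Reliability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution, quantile and random generation for the
    power-modified Lindley (PML) lifetime distribution, together with its
    moment and lifetime summaries (incomplete moments, mean residual life,
    mean inactivity time, mean deviations, Bonferroni and Lorenz curves,
    residual-life moments). Provides maximum-likelihood estimation with
    observed-information standard errors, goodness-of-fit statistics and
    comparisons against standard lifetime families, Bayesian estimation via
    random-walk Metropolis-Hastings under squared-error, LINEX and entropy
    loss with highest-posterior-density intervals, closed-form
    stress-strength reliability P(Y < X) with delta-method and Bayesian
    interval estimates, and a Monte-Carlo engine for benchmarking the
    estimators.  Ships three classic lifetime datasets (COVID-19 mortality
    rates, jute-fibre breaking strengths, bank waiting times) as plain-text
    fixtures and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tibble,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    ggplot2
Config/testthat/edition: 3
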