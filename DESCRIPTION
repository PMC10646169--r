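Package: songscape
Title: Hierarchical Density-Habitat Models for Songbird Point Counts
Version: 0.1.0
Authors@R: person("Songscape", "Maintainers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits hierarchical Bayesian density-habitat models to avian
    point-count data collected on 1-km2 survey grids. The observation
    process combines a removal model for availability over minute
    intervals with binned half-normal distance sampling; the state
    process is a zero-inflated Poisson with a log-linear habitat model,
    continuous spatial scale-of-effect (buffer radius) selection for
    landscape covariates, region-level random intercepts and population
    trends with an inverse-Wishart covariance, and a two-dimensional
    thin-plate spline on the zero-inflation probability. Includes a
    synthetic-study generator, MCMC fitting with convergence and
    posterior-predictive diagnostics, population trend classification,
    and predicted density mapping with quality-assurance masks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
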