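Package: gunpolicy
Title: Bayesian Panel Models for State Firearm Policy Effects
Version: 0.1.0
Authors@R: person("Panel", "Methods Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the effects of state firearm policies on
    firearm mortality from state-year panel data. Implements law coding into
    exposure and phase-in covariates, a debiased autoregressive negative
    binomial count model with population offsets, year effects, confounder
    and lasso-regularized covariates, informative priors on total policy
    effects, adaptive MCMC estimation with convergence diagnostics, posterior
    combination of joint policy-class effects (incidence rate ratios,
    credible intervals, probabilities of reduced deaths, deaths averted), a
    synthetic panel generator with confounded policy adoption, and a
    simulation-based calibration and attenuation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
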