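Package: agestoch
Title: Stochastic Demography of Age-Structured Populations
Version: 1.0.0
Authors@R: person("Avery", "Sloane", email = "avery.sloane@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how environmental variability shapes the
    growth of age-structured populations. Provides parametric age-specific
    mortality models (Gompertz, Gompertz-Makeham, Weibull, logistic, Siler
    bathtub and juvenile-decline composites) with maximum-likelihood fitting
    and model selection on age-at-death data; construction and calibration of
    Leslie matrices and their one-adult-stage reductions to a stationary
    deterministic growth rate; stochastic projection under environmental
    shocks with negative, null or positive covariation between survival and
    fecundity; exact decompositions of the mean and variance of the yearly
    growth rate; small-noise and second-order Taylor approximations to the
    long-run stochastic growth rate; Kullback-Leibler comparison of growth
    rate densities between full-age and stage-collapsed models; and
    extinction-time simulation with demographic stochasticity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
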