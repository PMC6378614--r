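# agestoch

Stochastic demography of age-structured populations: how the shape of
age-specific survival and fecundity, and the within-year covariation
between them, determine the mean, the variance and the long-run value of
the yearly population growth rate — and ultimately the time to
extinction.

`agestoch` is aimed at population ecologists who work with matrix
population models and want to go beyond the deterministic dominant
eigenvalue: it makes it easy to ask what happens to a life history under
environmental shocks that hit survival and fecundity together
(positively), independently, or in opposite directions (a within-year
survival–reproduction trade-off), and how much is lost when adult ages
are pooled into a single stage.

## The model

A population is classified by age `x = 0, 1, …, ω` with mean survival
probabilities `ρ_x` and fecundities `β_x` derived from parametric hazard
models (Gompertz, Gompertz–Makeham, two/three-parameter Weibull,
logistic, Siler bathtub, juvenile-decline composites). These fill a
Leslie matrix whose fecundity row is rescaled so the deterministic growth
rate is stationary (`λ_d = 1`). Each year a scalar environmental shock
`ε_t ~ N(0, σ²)` perturbs survival on the logit scale and a shock `δ_t`
perturbs fecundity on the log scale, with `δ_t = −ε_t`, independent, or
`+ε_t` in the three covariation scenarios. The yearly growth rate is

    λ_t = Σ_x w_{x,t−1} (b_{x,t} + p_{x,t}),

with `w_{x,t−1}` the age-structure proportions. The package computes the
exact sample decompositions

    E[λ_t]   = λ_e = λ̃ + C_wb + C_wp
    Var[λ_t] = V_λ = V_wp + V_wb + 2 C_x + 2 C_ij,

where `λ̃` uses time-averaged structure and rates, `C_wb`/`C_wp` are
summed covariances between lagged structure and current rates (zero in
expectation under iid environments), `V_wp`/`V_wb` are summed variances
of the products `w·p` and `w·b`, `C_x` their same-age covariances and
`C_ij` all cross-age covariances. Long-run growth is estimated three
ways: empirically (`r_e = mean ln λ_t`), by the second-order Taylor form
`r_T = ln λ_e − V_λ/(2 λ_e²)`, and by the small-noise approximation
`ln λ_0 − τ_0²/(2 λ_0²)` built from sensitivity-weighted covariances of
the matrix entries. Stage collapse, Kullback–Leibler comparison of
mean-growth-rate densities, mortality-model fitting on age-at-death data
(MLE/AIC, optional Metropolis DIC), and extinction simulation with
binomial survival and Poisson recruitment round out the toolkit.

## Worked example

A senescent (Gompertz) mortality preset crossed with early-hump
fecundity, under a survival–fecundity trade-off (σ = 0.3):

```r
library(agestoch)

presets   <- default_presets()
sched     <- make_schedules(presets$mortality$M1, presets$fecundity$F4)
full      <- calibrate_fecundity(sched)
collapsed <- collapse_adult_stage(full)
full
#> <projection_model> full_age, 24 classes, lambda_d = 1.00000000
#>   fecundity calibration scale c = 0.238634

sc  <- env_scenario("negative", sigma = 0.3, seed = 1)
run <- simulate_run(full, sc, T = 10000)
decompose_mean(run)
#> <mean_decomposition>
#>   lambda_e = 0.99742045 = lambda_tilde (0.99744594) + C_wb (-3.995e-05) + C_wp (1.446e-05)
decompose_variance(run)
#> <variance_decomposition>
#>   V_lambda = 1.548838e-04 = V_wp (6.685e-03) + V_wb (4.022e-04) + 2 C_x (7.626e-04) + 2 C_ij (-4.229e-03)
```

Both decompositions are exact identities of the simulated sample. The
variance components tell the trade-off story: the within-age survival
variance `V_wp` is large, but the cross-age covariances `C_ij` are
strongly negative and cancel most of it, leaving a yearly growth-rate
variance forty times smaller than `V_wp`.

```r
growth_rate_estimates(run)[, c("r_e", "r_T", "r_small_noise")]
#>            r_e          r_T r_small_noise
#> 1 -0.002660118 -0.002660727  -0.002593049
```

The Taylor approximation reproduces the empirical long-run rate to six
decimals; the small-noise form is close behind. Pooling adults into one
stage changes the picture drastically under a trade-off:

```r
ens_a <- ensemble_growth(full,      sc, R = 500, T = 200)
ens_c <- ensemble_growth(collapsed, sc, R = 500, T = 200)
kl_information(ens_a, ens_c)
#> <kl_result> KL = 203.022 nats (bandwidths a = 0.000483, c = 4.83e-05)
var(ens_c$lambda_bar) / var(ens_a$lambda_bar)
#> [1] 0.009218287
```

The one-adult-stage model concentrates its mean growth rates in a sliver
of the full-age model's density (two orders of magnitude less spread), so
approximating one with the other discards essentially all of the
information — the KL divergence is enormous.

Mortality-model selection on simulated age-at-death data recovers the
generating family:

```r
s <- sample_ages_at_death(presets$mortality$M1, 2000, seed = 42)
select_model(s, c("constant", "gompertz", "weibull2", "siler_bathtub"))
#> <model_selection> ranked by AIC
#>         family k    loglik      aic     delta
#>       gompertz 2 -5685.922 11375.84   0.00000
#>  siler_bathtub 5 -5683.650 11377.30   1.45564
#>       weibull2 2 -5796.053 11596.11 220.26305
#>       constant 1 -6057.480 12116.96 741.11641
```

The full experiment grid (25 mortality × fecundity combinations × 3
covariation scenarios, with ensembles, decompositions and KL tables) runs
from one call: `run_grid(list(scale = 0.1), out_dir = "out")` writes CSV
tables and a JSON manifest; `scale = 1` reproduces the full study sizes.

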