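# Shared fixtures, built in code. The calibrated preset grid is expensive
# enough to cache across test files.

.fixture_cache <- new.env(parent = emptyenv())

test_grid <- function() {
  if (is.null(.fixture_cache$grid)) .fixture_cache$grid <- make_grid()
  .fixture_cache$grid
}

# minimal two-age-class schedules: rho_0 = 0.5, terminal zero, flat
# fecundity 1 from birth
toy_schedules <- function() schedules(rho = c(0.5, 0), beta = c(1, 1),
                                      alpha = 0L)

# random hazard models across families, for property tests
random_hazard_model <- function(family) {
  r <- function(lo, hi) stats::runif(1, lo, hi)
  switch(family,
    constant = hazard_model("constant", c(c = r(0.01, 1))),
    gompertz = hazard_model("gompertz", c(a = r(0.01, 0.3), b = r(0, 0.4))),
    gompertz_makeham = hazard_model("gompertz_makeham",
      c(a = r(0.01, 0.3), b = r(0, 0.4), c = r(0, 0.3))),
    weibull2 = hazard_model("weibull2", c(a = r(0.5, 3), l = r(0.05, 0.8))),
    weibull3 = hazard_model("weibull3",
      c(a = r(0.5, 3), l = r(0.05, 0.8), c = r(0, 0.3))),
    logistic = hazard_model("logistic",
      c(a = r(0.01, 0.3), b = r(0.01, 0.4), s = r(0, 2))),
    siler_bathtub = hazard_model("siler_bathtub",
      c(a1 = r(0.05, 1), b1 = r(0.1, 2), c = r(0, 0.2),
        a2 = r(0.005, 0.1), b2 = r(0.05, 0.3))),
    juvenile_plus_adult = hazard_model("juvenile_plus_adult",
      c(a1 = r(0.05, 1), b1 = r(0.1, 2)),
      adult = hazard_model("gompertz", c(a = r(0.01, 0.3), b = r(0, 0.4))))
  )
}

all_families <- c("constant", "gompertz", "gompertz_makeham", "weibull2",
                  "weibull3", "logistic", "siler_bathtub",
                  "juvenile_plus_adult")
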