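# Death-density likelihood, MLE, and model selection.

test_that("log-likelihood matches the closed form", {
  # single death at x = 2 under constant hazard 0.5: ln 0.5 - 1
  expect_equal(loglik_ages("constant", 0.5, 2), log(0.5) - 1)
  # deaths at 0 under unit hazard contribute ln 1 - 0 each
  expect_equal(loglik_ages("constant", 1, c(0, 0)), 0)
  # nesting: gompertz with b = 0 equals the constant likelihood
  x <- c(0.5, 1.2, 3.7, 8)
  expect_equal(loglik_ages("gompertz", c(0.3, 0), x),
               loglik_ages("constant", 0.3, x), tolerance = 1e-10)
  # out-of-domain parameters are -Inf by contract
  expect_identical(loglik_ages("gompertz", c(-1, 0.1), x), -Inf)
  # left truncation adds back the survival to the truncation age
  expect_equal(loglik_ages("constant", 0.5, c(3, 4), truncation = 2),
               sum(log(0.5) - 0.5 * c(3, 4)) + 2 * 0.5 * 2)
  expect_error(loglik_ages("constant", 0.5, c(1, 3), truncation = 2),
               "below the truncation")
})

test_that("the constant-hazard MLE matches its closed form", {
  fit <- fit_mle("constant", c(1, 2, 3))
  expect_true(fit$converged)
  expect_equal(unname(fit$mle_params["c"]), 0.5, tolerance = 1e-6)
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
})

test_that("Gompertz parameters are recovered from simulated deaths", {
  s <- sample_ages_at_death(hazard_model("gompertz", c(a = 0.02, b = 0.15)),
                            2000, seed = 31)
  fit <- fit_mle("gompertz", s, seed = 2)
  expect_true(fit$converged)
  expect_lt(abs(fit$mle_params[["a"]] - 0.02) / 0.02, 0.15)
  expect_lt(abs(fit$mle_params[["b"]] - 0.15) / 0.15, 0.15)
})

test_that("fitting contracts are enforced", {
  expect_error(fit_mle("gompertz_makeham", c(2)), "sample size")
  expect_error(fit_mle("no_such_family", c(1, 2, 3)), "unknown family")
  expect_error(select_model(c(1, 2, 3), "constant"), "at least 2")
})

test_that("model selection identifies the generating family", {
  s <- sample_ages_at_death(hazard_model("gompertz", c(a = 0.05, b = 0.3)),
                            1000, seed = 13)
  sel <- select_model(s, c("constant", "gompertz"))
  expect_identical(sel$table$family[1L], "gompertz")
  expect_true(all(diff(sel$table[[sel$criterion]]) >= 0))
  expect_equal(sel$table$delta[1L], 0)
})

test_that("AIC ranking is invariant to a consistent age-unit rescaling", {
  s <- sample_ages_at_death(hazard_model("gompertz", c(a = 0.05, b = 0.25)),
                            1500, seed = 17)
  sel_y <- select_model(s$ages, c("constant", "gompertz", "weibull2"))
  sel_m <- select_model(s$ages * 12, c("constant", "gompertz", "weibull2"))
  expect_identical(sel_y$table$family, sel_m$table$family)
  # the Jacobian of the time rescaling shifts every AIC equally
  expect_equal(sel_y$table$delta, sel_m$table$delta, tolerance = 0.02)
})

test_that("Metropolis DIC agrees with AIC on an easy contrast", {
  # strongly senescent deaths: the age-dependent model must win under DIC
  s <- sample_ages_at_death(hazard_model("gompertz", c(a = 0.05, b = 0.3)),
                            500, seed = 19)
  sel <- select_model(s, c("constant", "gompertz"), criterion = "dic",
                      iter = 3000L, burn_in = 1000L)
  expect_identical(sel$table$family[1L], "gompertz")
  d <- dic_metropolis("gompertz", s, iter = 3000L, burn_in = 1000L,
                      seed = 3)
  expect_true(is.finite(d$dic))
  # effective number of parameters near the two free parameters
  expect_gt(d$p_d, 0.3)
  expect_lt(d$p_d, 5)
})
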