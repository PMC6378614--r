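# Information loss, sigma sweeps, extinction, grid driver.

test_that("KL information loss behaves as a divergence", {
  set.seed(4)
  a <- stats::rnorm(300, 1, 0.02)
  expect_lt(kl_information(a, a)$kl, 1e-6)
  bw <- stats::bw.nrd0(a)
  shifted <- a + 5 * bw
  expect_gt(kl_information(a, shifted)$kl, 1)
  # asymmetry on unequal-spread samples
  wide <- stats::rnorm(300, 1, 0.08)
  expect_false(isTRUE(all.equal(kl_information(a, wide)$kl,
                                kl_information(wide, a)$kl)))
  expect_gt(kl_information(a, wide)$kl, -1e-9)
  expect_error(kl_information(a[1:5], a), "at least 10")
  expect_warning(kl_information(rep(1, 20), a), "degenerate")
})

test_that("independent ensembles from one regime are close in KL", {
  model <- test_grid()[["M1-F4"]]$full
  e1 <- ensemble_growth(model, env_scenario("negative", 0.3, seed = 9),
                        R = 2000, T = 200)
  e2 <- ensemble_growth(model, env_scenario("negative", 0.3, seed = 10),
                        R = 2000, T = 200)
  expect_lt(kl_information(e1, e2)$kl, 0.05)
})

test_that("a zero-sigma sweep gives the deterministic components", {
  tab <- sweep_sigma(test_grid()[["M3-F1"]], "null", 0, T = 200, seed = 1)
  expect_identical(nrow(tab), 2L)
  expect_true(all(abs(tab$lambda_e - 1) < 1e-10))
  expect_true(all(tab$V_lambda < 1e-20))
})

test_that("mean growth can rise with environmental variance under a trade-off", {
  # declining-mortality life histories show the clearest increase of
  # lambda_e with sigma under negative covariation in this preset grid
  tab <- sweep_sigma(test_grid()[["M5-F3"]], "negative",
                     c(0.05, 0.15, 0.3), T = 8000, seed = 5)
  le <- tab$lambda_e[tab$model == "full"]
  expect_true(all(diff(le) > 0))
  expect_gt(le[3], 1)
})

test_that("extinction summaries respect their contracts", {
  model <- test_grid()[["M1-F1"]]$full
  ex <- extinction_experiment(model, "positive", sigmas = 0.8, R = 20,
                              T = 300, N0 = 0, seed = 1)
  expect_equal(ex$summary$fraction_extinct, 1)
  expect_equal(ex$summary$mean_time_extinct, 0)
  ex2 <- extinction_experiment(model, "positive", sigmas = c(0.5, 0.9),
                               R = 30, T = 300, N0 = 200, seed = 2)
  expect_true(all(ex2$summary$fraction_extinct >= 0 &
                    ex2$summary$fraction_extinct <= 1))
  expect_identical(nrow(ex2$summary), 2L)
})

test_that("the grid driver is deterministic and complete at small scale", {
  cfg <- list(combos = c("M1-F1", "M2-F4"), sigma = 0.2,
              ensembles = list(R = 12L, T = 50L, burn_in = 0L),
              decomposition = list(T = 80L))
  t0 <- Sys.time()
  r1 <- run_grid(cfg)
  elapsed <- as.numeric(Sys.time() - t0, units = "secs")
  expect_lt(elapsed, 60)
  r2 <- run_grid(cfg)
  expect_identical(r1$ensembles, r2$ensembles)
  expect_identical(r1$kl, r2$kl)
  expect_identical(r1$components, r2$components)
  expect_identical(nrow(r1$kl), 6L)                 # 2 combos x 3 scenarios
  expect_identical(nrow(r1$ensembles), 2L * 3L * 2L * 12L)
  expect_true(all(r1$kl$kl > -1e-9))
  expect_error(run_grid(list(combos = "M9-F9")), "unknown combo")
})
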