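# Structure propagation, ensembles, and demographic stochasticity.

test_that("one projection step matches hand arithmetic", {
  st <- project_step(c(0.6, 0.4), p = c(0.5, 0), b = c(1, 1), "full_age")
  expect_equal(st$lambda, 1.3)
  expect_equal(st$w, c(1 / 1.3, 0.3 / 1.3))
  expect_false(st$degenerate)
  # total demographic failure
  st0 <- project_step(c(0.6, 0.4), p = c(0, 0), b = c(0, 0), "full_age")
  expect_identical(st0$lambda, 0)
  expect_true(st0$degenerate)
  expect_error(project_step(c(0.6, 0.6), c(0.5, 0), c(1, 1)), "sum to 1")
})

test_that("the calibrated model is a deterministic fixed point", {
  model <- test_grid()[["M1-F1"]]$full
  run <- simulate_run(model, env_scenario("null", 0, seed = 1), 100)
  expect_true(all(abs(run$lambda - 1) < 1e-10))
  expect_lt(max(abs(run$w[, 101] - model$w)), 1e-10)
})

test_that("runs are reproducible and conserve structure", {
  model <- test_grid()[["M2-F3"]]$full
  sc <- env_scenario("negative", 0.3, seed = 33)
  r1 <- simulate_run(model, sc, 300)
  r2 <- simulate_run(model, sc, 300)
  expect_identical(r1$lambda, r2$lambda)
  expect_lt(max(abs(colSums(r1$w) - 1)), 1e-12)
  expect_true(all(r1$lambda > 0))
})

test_that("structure-weighted growth equals raw abundance growth", {
  model <- test_grid()[["M4-F2"]]$full
  run <- simulate_run(model, env_scenario("positive", 0.4, seed = 55), 100)
  N <- model$w * 1e6
  for (t in 1:100) {
    A_t <- agestoch:::.assemble_matrix(run$p[, t], run$b[, t], "full_age")
    N_next <- drop(A_t %*% N)
    expect_equal(run$lambda[t], sum(N_next) / sum(N), tolerance = 1e-10)
    N <- N_next
  }
})

test_that("a run with no production path truncates with a warning", {
  model <- agestoch:::.projection_model(survival = c(0.5, 0),
                                        fecundity = c(0, 0),
                                        kind = "full_age",
                                        classes = c("0", "1"), alpha = 0L)
  expect_warning(
    run <- simulate_run(model, env_scenario("null", 0, seed = 1), 10,
                        w0 = c(1, 0)),
    "degenerate")
  expect_true(run$degenerate)
  expect_lt(run$T, 10L)
})

test_that("ensembles degenerate to the deterministic rate at sigma zero", {
  model <- test_grid()[["M3-F2"]]$full
  ens <- ensemble_growth(model, env_scenario("null", 0, seed = 5),
                         R = 20, T = 50)
  expect_true(all(abs(ens$lambda_bar - 1) < 1e-10))
})

test_that("averaging over longer runs shrinks the ensemble variance", {
  model <- test_grid()[["M1-F4"]]$full
  v <- vapply(c(50L, 200L, 800L), function(T) {
    ens <- ensemble_growth(model, env_scenario("null", 0.2, seed = 12),
                           R = 200, T = T)
    stats::var(ens$lambda_bar)
  }, numeric(1))
  expect_true(v[1] > v[2] && v[2] > v[3])
})

test_that("demographic runs respect conservation and absorption", {
  # an immortal sterile class conserves its count forever
  im <- agestoch:::.projection_model(survival = 1, fecundity = 0,
                                     kind = "one_adult_stage",
                                     classes = "adult", alpha = 0L)
  dr <- demographic_run(im, env_scenario("null", 0, seed = 1), N0 = 100L,
                        T = 50L)
  expect_true(all(dr$N == 100L))
  expect_false(dr$extinct)
  # an empty population is extinct at time zero and stays empty
  model <- test_grid()[["M1-F1"]]$full
  dr0 <- demographic_run(model, env_scenario("null", 0.2, seed = 2),
                         N0 = 0L, T = 10L)
  expect_identical(dr0$extinction_time, 0L)
  expect_true(all(dr0$N == 0L))
})

test_that("large populations track the environmental growth series", {
  model <- test_grid()[["M2-F1"]]$full
  sc <- env_scenario("negative", 0.3, seed = 77)
  env <- simulate_run(model, sc, 100)
  dem <- demographic_run(model, sc, N0 = 1000000L, T = 100L)
  expect_false(dem$extinct)
  g_dem <- dem$N[-1] / dem$N[-101]
  expect_lt(max(abs(g_dem / env$lambda - 1)), 0.05)
})

test_that("stationary populations neither grow nor shrink on average", {
  model <- test_grid()[["M1-F1"]]$full
  drift <- vapply(1:100, function(r) {
    dr <- demographic_run(model, env_scenario("null", 0, seed = 1),
                          N0 = 1000L, T = 2000L, seed = derive_seed(900L, r))
    if (dr$extinct) NA_real_ else log(dr$N[2001L] / 1000) / 2000
  }, numeric(1))
  expect_lt(abs(mean(drift, na.rm = TRUE)), 0.01)
})
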