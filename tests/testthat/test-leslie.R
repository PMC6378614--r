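# Leslie construction, eigen-analysis, calibration, stage collapse.

test_that("Leslie matrix places fecundities and survivals correctly", {
  m <- build_leslie(toy_schedules())
  expect_equal(m$matrix, matrix(c(1, 0.5, 1, 0), 2, 2))
  eig <- dominant_eigen(m)
  expect_equal(eig$lambda, (1 + sqrt(3)) / 2, tolerance = 1e-10)
  expect_equal(eig$w, c(1, 0.5 / eig$lambda) / (1 + 0.5 / eig$lambda),
               tolerance = 1e-8)
  expect_equal(sum(eig$v * eig$w), 1, tolerance = 1e-12)
})

test_that("degenerate structures are handled", {
  # identity matrix: dominant eigenvalue 1
  expect_equal(dominant_eigen(diag(3))$lambda, 1)
  # no reproduction: nilpotent matrix, spectral radius 0 (< 1)
  m <- build_leslie(schedules(rho = c(0.5, 0), beta = c(0, 0)))
  expect_lt(dominant_eigen(m)$lambda, 1)
  expect_error(dominant_eigen(matrix(c(1, -0.1, 0, 1), 2)), "non-negative")
  expect_error(calibrate_fecundity(schedules(rho = c(0.5, 0),
                                             beta = c(0, 0))),
               "reproductive path")
})

test_that("calibration finds the stationary fecundity scale", {
  cal <- calibrate_fecundity(toy_schedules())
  # lambda = 1 requires 1 - c - 0.5 c = 0
  expect_equal(cal$calibration_scale, 2 / 3, tolerance = 1e-9)
  expect_equal(cal$lambda_d, 1, tolerance = 1e-10)
  # idempotence: calibrating an already-stationary model returns scale 1
  s2 <- schedules(rho = c(0.5, 0), beta = (2 / 3) * c(1, 1))
  expect_equal(calibrate_fecundity(s2)$calibration_scale, 1,
               tolerance = 1e-10)
})

test_that("column sums equal per-class production for both model kinds", {
  g <- test_grid()
  set.seed(7)
  for (cell in g[c("M1-F1", "M2-F4", "M5-F5")]) {
    for (kind in c("full", "collapsed")) {
      model <- cell[[kind]]
      n <- length(model$survival)
      w <- stats::runif(n); w <- w / sum(w)
      lhs <- sum(w * (model$fecundity + model$survival))
      rhs <- sum(model$matrix %*% w)
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("grid models have a simple positive Perron pair", {
  g <- test_grid()
  for (cell in g) {
    expect_gt(min(cell$full$w), 0)
    expect_gt(min(cell$full$v), 0)
    expect_gt(min(cell$collapsed$w), 0)
  }
})

test_that("stage collapse reproduces constant adult rates", {
  # adult survival and fecundity constant across ages: the collapsed
  # constants must equal them and the recalibration must be a no-op (up
  # to the terminal-age truncation, negligible at omega = 50)
  omega <- 50
  rho <- c(rep(0.8, omega), 0)
  beta <- c(0, 0, rep(0.5, omega - 1))
  full <- calibrate_fecundity(schedules(rho, beta, alpha = 2L))
  col <- collapse_adult_stage(full)
  const <- attr(col, "adult_constants")
  expect_equal(unname(const["p_c"]), 0.8, tolerance = 1e-3)
  expect_equal(unname(const["b_c"]),
               unname(full$fecundity[3L]), tolerance = 1e-3)
  expect_equal(unname(const["rescale"]), 1, tolerance = 1e-3)
  expect_equal(col$lambda_d, 1, tolerance = 1e-10)
  expect_identical(col$classes, c("0", "1", "adult"))
})

test_that("collapse at the boundary alpha = omega keeps all ages", {
  full <- calibrate_fecundity(schedules(rho = c(0.9, 0.8, 0),
                                        beta = c(0, 0, 1), alpha = 2L))
  col <- collapse_adult_stage(full, alpha = 2L)
  expect_length(col$classes, 3L)
  # the "adult" class is the single terminal age: self-loop survival 0
  expect_identical(unname(col$survival[3L]), 0)
  expect_error(collapse_adult_stage(full, alpha = 5L), "alpha")
})

test_that("projection models export to CSV and JSON", {
  cal <- calibrate_fecundity(toy_schedules())
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  export_projection_model(cal, csv, js)
  m <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(unname(as.matrix(m[, -1])), unname(cal$matrix),
               tolerance = 1e-12)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$lambda_d, 1, tolerance = 1e-8)
  expect_equal(meta$calibration_scale, 2 / 3, tolerance = 1e-6)
})
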