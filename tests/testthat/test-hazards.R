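# Hazard families, cumulative hazards, discrete survival, truncation.

test_that("hazard evaluations match hand-derived values and limits", {
  # b = 0 collapses Gompertz to a constant hazard
  expect_equal(hazard(hazard_model("gompertz", c(a = 0.1, b = 0)), 5), 0.1)
  # Siler at age zero: a1 e^0 + c + a2 e^0 with a1 = 0
  m <- hazard_model("siler_bathtub",
                    c(a1 = 0, b1 = 1, c = 0.02, a2 = 0.01, b2 = 0.1))
  expect_equal(hazard(m, 0), 0.03)
  # s = 0 removes the logistic denominator
  x <- c(0, 1, 3.5, 10)
  expect_equal(hazard(hazard_model("logistic", c(a = 0.05, b = 0.1, s = 0)), x),
               hazard(hazard_model("gompertz", c(a = 0.05, b = 0.1)), x))
})

test_that("parameter domain is enforced", {
  expect_error(hazard_model("gompertz", c(a = -0.1, b = 0.2)), "negative")
  expect_error(hazard_model("gompertz", c(a = 0.1)), "named parameters")
  expect_error(hazard_model("juvenile_plus_adult", c(a1 = 0.5, b1 = 1)),
               "adult")
  expect_error(hazard_model("juvenile_plus_adult", c(a1 = 0.5, b1 = 1),
                            adult = hazard_model("constant", c(c = 0.1))),
               "gompertz")
  expect_error(hazard(hazard_model("constant", c(c = 0.1)), -1), ">= 0")
})

test_that("cumulative hazard closed forms are exact", {
  expect_equal(cumulative_hazard(hazard_model("constant", c(c = 0.1)), 10),
               1.0)
  gm <- hazard_model("gompertz", c(a = 0.1, b = 0.2))
  expect_identical(cumulative_hazard(gm, 0), 0)
  expect_equal(cumulative_hazard(gm, 5), (0.1 / 0.2) * expm1(1),
               tolerance = 1e-12)
})

test_that("closed-form and quadrature cumulative hazards agree", {
  set.seed(41)
  for (i in 1:100) {
    fam <- sample(all_families, 1)
    m <- random_hazard_model(fam)
    x <- stats::runif(1, 0.1, 15)
    expect_equal(cumulative_hazard(m, x, "quadrature"),
                 cumulative_hazard(m, x, "closed"),
                 tolerance = 1e-8)
  }
})

test_that("survivorship is non-increasing for every family", {
  set.seed(42)
  ages <- seq(0, 40, by = 0.5)
  for (fam in all_families) {
    for (i in 1:10) {
      m <- random_hazard_model(fam)
      S <- exp(-cumulative_hazard(m, ages))
      expect_true(all(diff(S) <= 1e-14),
                  info = sprintf("family %s draw %d", fam, i))
    }
  }
})

test_that("nested-model limits agree pointwise", {
  x <- c(0, 0.5, 2, 7, 20)
  gm <- hazard_model("gompertz", c(a = 0.07, b = 0.12))
  mk0 <- hazard_model("gompertz_makeham", c(a = 0.07, b = 0.12, c = 0))
  expect_equal(hazard(mk0, x), hazard(gm, x), tolerance = 1e-12)
  expect_equal(cumulative_hazard(mk0, x), cumulative_hazard(gm, x),
               tolerance = 1e-12)
  mk <- hazard_model("gompertz_makeham", c(a = 0.07, b = 0.12, c = 0.03))
  si0 <- hazard_model("siler_bathtub",
                      c(a1 = 0, b1 = 1, c = 0.03, a2 = 0.07, b2 = 0.12))
  expect_equal(hazard(si0, x), hazard(mk, x), tolerance = 1e-12)
  expect_equal(cumulative_hazard(si0, x), cumulative_hazard(mk, x),
               tolerance = 1e-12)
  lg0 <- hazard_model("logistic", c(a = 0.07, b = 0.12, s = 0))
  expect_equal(cumulative_hazard(lg0, x), cumulative_hazard(gm, x),
               tolerance = 1e-12)
})

test_that("annual survival is the survivorship ratio over one age step", {
  expect_equal(annual_survival(hazard_model("constant", c(c = 0)), 0:5),
               rep(1, 6))
  expect_equal(annual_survival(hazard_model("constant", c(c = 0.1)), 3),
               exp(-0.1))
  # senescent hazard: survival declines monotonically towards zero
  # (ages capped where survival is still representable above underflow)
  p <- annual_survival(hazard_model("gompertz", c(a = 0.05, b = 0.3)), 0:30)
  expect_true(all(diff(p) < 0))
  expect_lt(p[31], 1e-10)
  # Weibull shape < 1: hazard diverges at 0 but the increment is finite
  wb <- hazard_model("weibull2", c(a = 0.5, l = 0.3))
  expect_identical(hazard(wb, 0), Inf)
  expect_true(annual_survival(wb, 0) > 0 && annual_survival(wb, 0) < 1)
})

test_that("truncation age is the first age below the survivorship floor", {
  m <- hazard_model("constant", c(c = 0.5))
  expect_identical(truncation_age(m, 1e-4), 19L)
  expect_identical(truncation_age(m, 0.5), 2L)
  expect_identical(truncation_age(m, 0.999), 1L)
  expect_error(truncation_age(m, 0), "in \\(0, 1\\)")
  expect_warning(w <- truncation_age(hazard_model("constant", c(c = 0.001)),
                                     1e-4, cap = 50L),
                 "cap")
  expect_identical(w, 50L)
})
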