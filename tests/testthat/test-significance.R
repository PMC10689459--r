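test_that("correction term matches hand evaluation", {
  expect_equal(correction_term(4), 0.25)
  expect_equal(correction_term(10), 1 / 133.6)
  expect_equal(correction_term(17), 1 / (13^4 / 17 + 4))
  expect_true(correction_term(50) > 0 && correction_term(50) <= 0.25)
  expect_error(correction_term(3), "n >= k")
})

test_that("effective degrees of freedom match hand evaluation and grow with n", {
  expect_equal(effective_dfd(10), (0.8 - 1 / 133.6) * 7.5)
  expect_equal(effective_dfd(10), 5.943862, tolerance = 1e-6)
  expect_equal(effective_dfd(17), 11.59139, tolerance = 1e-6)
  expect_equal(effective_dfd(5), (0.8 - 5 / 21) * 2.5)
  expect_equal(effective_dfd(4), 0.825)
  expect_true(all(diff(effective_dfd(4:60)) > 0))
  expect_error(effective_dfd(3), "n >= 4")
})

test_that("recalibrated F-value uses the n/k scaling", {
  expect_equal(f_value(1, 1, 10), 0)
  expect_equal(f_value(2, 1, 10), 2.5)
  expect_equal(f_value(1.5, 1, 16), 2)
  expect_identical(f_value(2, 0, 10), Inf)
  expect_error(f_value(1, 2, 10), "sse_m1 <= sse_m0")
})

test_that("classical F-value keeps the linear-model scaling", {
  expect_equal(f_value_classical(2, 1, 10, k = 4, j = 1), 2)
  expect_equal(f_value_classical(1, 1, 10), 0)
  expect_error(f_value_classical(2, 1, 4), "n > k")
})

test_that("p-values follow the shifted null distribution", {
  # below the location shift there is no null mass
  expect_equal(p_value(0, 10), 1)
  expect_equal(p_value(0.12, 10), 1)
  expect_equal(p_value(1e8, 10), 0, tolerance = 1e-10)
  # frozen quadrature oracle: integral of the F(5, dfd(10)) density
  # over [3 - 0.12, Inf)
  expect_equal(p_value(3, 10), 0.1160879480, tolerance = 1e-8)
  # monotone non-increasing in F, continuous at the shift
  f <- seq(0, 20, by = 0.05)
  p <- p_value(f, 10)
  expect_true(all(diff(p) <= 0))
  expect_equal(p_value(0.12 + 1e-12, 10), 1, tolerance = 1e-9)
  # log10 path agrees with the linear path
  expect_equal(10^p_value(c(1, 5, 30), 10, log10p = TRUE),
               p_value(c(1, 5, 30), 10))
})

test_that("null-curve simulation is reproducible and centered at 1", {
  a <- simulate_null_curves(50, seed = 101)
  b <- simulate_null_curves(50, seed = 101)
  expect_identical(lapply(a, `[[`, "y"), lapply(b, `[[`, "y"))
  big <- simulate_null_curves(10000, seed = 102)
  ybar <- mean(vapply(big, function(cv) mean(cv$y), 0))
  expect_lt(abs(ybar - 1), 0.01)
  # zero variance gives exactly flat curves and F = 0 after fitting
  flat <- simulate_null_curves(3, variance_source = function(m) rep(0, m),
                               seed = 103)
  for (cv in flat) {
    expect_true(all(cv$y == 1))
    fit <- fit_loglogistic(cv)
    expect_equal(f_value(fit$sse_m0, fit$sse_m1, cv$n), 0)
  }
})

test_that("F is invariant to rescaling the residual noise for interior fits", {
  # The model family is closed under affine response maps, so rescaling the
  # noise rescales both SSEs equally and leaves F unchanged -- exactly, as
  # long as no plateau box bound is active (the bounds are fixed in
  # response units, so bound-active optima are legitimately scale
  # dependent). Tight optimizer tolerance isolates the mathematical
  # property from convergence noise.
  set.seed(104)
  ctl <- fit_control(tol = 1e-13)
  b <- default_bounds(std_doses)
  interior <- function(f) {
    all(f$params > b$lower + 1e-9) && all(f$params < b$upper - 1e-9)
  }
  n_checked <- 0
  for (i in 1:60) {
    e <- rnorm(10)
    f1 <- fit_loglogistic(curve_data(std_doses, 1 + 0.05 * e), control = ctl)
    f2 <- fit_loglogistic(curve_data(std_doses, 1 + 0.10 * e), control = ctl)
    if (!(interior(f1) && interior(f2))) next
    n_checked <- n_checked + 1
    F1 <- f_value(f1$sse_m0, f1$sse_m1, 10)
    F2 <- f_value(f2$sse_m0, f2$sse_m1, 10)
    expect_lt(abs(F1 - F2) / max(F1, 1e-12), 1e-9)
  }
  expect_gt(n_checked, 10)
})

test_that("calibration report summarises empirical uniformity", {
  p <- (1:10000 - 0.5) / 10000
  rep <- calibration_report(p)
  expect_equal(unname(rep$fraction_below), c(0.01, 0.05, 0.1, 0.5),
               tolerance = 1e-3)
  expect_lt(rep$ks_distance, 1e-3)
  rep1 <- suppressWarnings(calibration_report(rep(1, 50)))
  expect_equal(unname(rep1$fraction_below[2]), 0)
  expect_error(calibration_report(c(0.5, 2)), "0, 1")
})
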