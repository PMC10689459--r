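test_that("log-logistic evaluation matches direct substitution and plateau limits", {
  p <- c(pEC50 = 7, slope = 1, front = 1, back = 0)
  # inflection point gives the midpoint of the plateaus
  expect_equal(loglogistic_eval(p, -7), 0.5)
  # one decade past the inflection: 1 / (1 + 10)
  expect_equal(loglogistic_eval(p, -6), 1 / 11)
  # plateau limits
  expect_equal(loglogistic_eval(p, -1e6), 1)
  expect_equal(loglogistic_eval(p, 1e6), 0)
  p2 <- c(pEC50 = 6.2, slope = 2.3, front = 0.8, back = 1.9)
  expect_equal(loglogistic_eval(p2, -1e6), 0.8)
  expect_equal(loglogistic_eval(p2, 1e6), 1.9)
  # response stays between the plateaus
  x <- seq(-12, 0, length.out = 101)
  y <- loglogistic_eval(p2, x)
  expect_true(all(y >= 0.8 & y <= 1.9))
})

test_that("log-logistic evaluation rejects invalid parameters", {
  expect_error(loglogistic_eval(c(pEC50 = NA, slope = 1, front = 1, back = 0), 0),
               "invalid")
  expect_error(loglogistic_eval(c(pEC50 = 7, slope = -1, front = 1, back = 0), 0),
               "slope")
})

test_that("evaluation is monotone in dose for fixed parameters", {
  set.seed(41)
  x <- seq(-10, -2, length.out = 50)
  for (i in 1:25) {
    p <- c(pEC50 = runif(1, 3, 9), slope = runif(1, 0.1, 5),
           front = runif(1, 0.2, 2), back = runif(1, 0.2, 2))
    y <- loglogistic_eval(p, x)
    d <- diff(y)
    if (p[["front"]] > p[["back"]]) expect_true(all(d <= 0))
    else if (p[["front"]] < p[["back"]]) expect_true(all(d >= 0))
  }
})

test_that("analytic gradient agrees with central finite differences", {
  # plateau limits of the partials
  p <- c(pEC50 = 7, slope = 1, front = 1, back = 0.2)
  g <- loglogistic_gradient(p, c(-1e6, 1e6, -7))
  expect_equal(unname(g[1, "front"]), 1)
  expect_equal(unname(g[1, "back"]), 0)
  expect_equal(unname(g[2, "front"]), 0)
  expect_equal(unname(g[2, "back"]), 1)
  # slope partial vanishes at the inflection
  expect_equal(unname(g[3, "slope"]), 0)

  set.seed(42)
  for (i in 1:1000) {
    p <- c(pEC50 = runif(1, 1, 13), slope = runif(1, 0.05, 10),
           front = runif(1, 0.1, 3), back = runif(1, 0.1, 3))
    x <- runif(3, -11, -3)
    expect_lt(max(abs(loglogistic_gradient(p, x) - fd_gradient(p, x))), 1e-5)
  }
})

test_that("mean model fit is the weighted mean with its weighted SSE", {
  f <- mean_model_fit(curve_data(1:3, c(1, 1, 1)))
  expect_equal(f$intercept, 1)
  expect_equal(f$sse, 0)
  f2 <- mean_model_fit(curve_data(1:2, c(0.8, 1.2)))
  expect_equal(f2$intercept, 1)
  expect_equal(f2$sse, 0.08)
  expect_equal(f2$rmse, sqrt(0.04))
  f3 <- mean_model_fit(curve_data(1:2, c(1, 2), w = c(3, 1)))
  expect_equal(f3$intercept, 1.25)
  expect_error(mean_model_fit(curve_data(numeric(0), numeric(0))), "empty")
})

test_that("curve fold change reflects plateau ratio and direction", {
  flat <- c(pEC50 = 7, slope = 1, front = 0.8, back = 0.8)
  expect_identical(fold_change(flat, -10, -4), 0)
  # saturated 4-fold loss, >= 3 decades of saturation on either side:
  # log2(0.25 / 1) = -2 up to the residual 1/(1+10^3) tail
  dn <- c(pEC50 = 7, slope = 1, front = 1, back = 0.25)
  expect_equal(fold_change(dn, -10, -4), -2, tolerance = 5e-3)
  # saturated doubling
  up <- c(pEC50 = 7, slope = 1, front = 0.5, back = 1)
  expect_equal(fold_change(up, -10, -4), 1, tolerance = 5e-3)
  # control-relative mode uses the control reference, not the low-dose model
  expect_equal(fold_change(dn, -10, -4, mode = "control", y_control = 1),
               log2(loglogistic_eval(dn, -4)))
  expect_error(fold_change(c(pEC50 = 7, slope = 1, front = 1, back = -1),
                           -10, -4), "positive")
})

test_that("curve_data validates, sorts and drops missing pairs", {
  cv <- curve_data(c(-5, -9, -7), c(0.5, 1, NA), curve_id = "a")
  expect_equal(cv$n, 2)
  expect_equal(cv$x, c(-9, -5))
  expect_equal(cv$y, c(1, 0.5))
  expect_error(curve_data(1:3, 1:2), "equal length")
  expect_error(curve_data(1:2, 1:2, w = c(-1, 1)), "non-negative")
  expect_equal(control_pseudo_dose(c(-9, -4)), -11)
  expect_error(control_pseudo_dose(numeric(0)))
})
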