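test_that("noise-free curves are recovered essentially exactly", {
  truth <- c(pEC50 = 7, slope = 1, front = 1, back = 0.3)
  fit <- fit_loglogistic(toy_curve())
  expect_lt(max(abs(fit$params - truth)), 1e-3)
  expect_lt(fit$sse_m1, 1e-12)
  expect_true(fit$converged)
})

test_that("constant data is fitted by a flat curve with zero fold change", {
  cv <- curve_data(std_doses, rep(0.9, 10))
  fit <- fit_loglogistic(cv)
  expect_lte(fit$sse_m1, fit$sse_m0 * (1 + 1e-9) + 1e-12)
  expect_lt(abs(fold_change(fit$params, min(cv$x), max(cv$x))), 1e-6)
})

test_that("orientation follows the data: decreasing responses give front > back", {
  set.seed(11)
  cv <- toy_curve(front = 1, back = 0.4, sd = 0.02)
  fit <- fit_loglogistic(cv)
  expect_gt(fit$params[["front"]], fit$params[["back"]])
  cv_up <- toy_curve(front = 0.5, back = 1.4, sd = 0.02)
  fit_up <- fit_loglogistic(cv_up)
  expect_lt(fit_up$params[["front"]], fit_up$params[["back"]])
})

test_that("fitted SSE never exceeds the mean-model SSE", {
  set.seed(12)
  for (i in 1:30) {
    cv <- curve_data(std_doses, 1 + rnorm(10, sd = runif(1, 0.01, 0.3)))
    fit <- fit_loglogistic(cv)
    expect_lte(fit$sse_m1, fit$sse_m0 * (1 + 1e-9) + 1e-12)
  }
})

test_that("start grid has the documented structure", {
  cv <- toy_curve(sd = 0)
  g <- build_start_grid(cv)
  expect_equal(nrow(g), 7 * 3 * 2)
  expect_equal(colnames(g), c("pEC50", "slope", "front", "back"))
  # pEC50 starts span the negated experimental range
  expect_equal(range(g[, "pEC50"]), c(-max(cv$x), -min(cv$x)))
  # both orientations present
  expect_true(any(g[, "front"] > g[, "back"]) && any(g[, "front"] < g[, "back"]))
  # constant responses give front = back starts
  gc <- build_start_grid(curve_data(std_doses, rep(1, 10)))
  expect_true(all(gc[, "front"] == gc[, "back"]))
  expect_equal(nrow(gc), 7 * 3)
})

test_that("curves below the minimum point count are refused", {
  cv <- curve_data(-6, 0.5)
  expect_equal(nrow(build_start_grid(cv)), 3)  # single pEC50 position
  expect_error(fit_loglogistic(cv), "usable points")
})

test_that("Gaussian negative log-likelihood matches the closed form", {
  cv <- curve_data(std_doses[1:4], loglogistic_eval(
    c(pEC50 = 7, slope = 1, front = 1, back = 0.3), std_doses[1:4]))
  p <- c(pEC50 = 7, slope = 1, front = 1, back = 0.3)
  # zero residuals, sigma2 = 1: n/2 * log(2*pi)
  expect_equal(negative_log_likelihood(p, 1, cv), 2 * log(2 * pi))
  # SSE = 2, sigma2 = 1, n = 4: 2 log(2 pi) + 1
  cv2 <- curve_data(std_doses[1:4], loglogistic_eval(p, std_doses[1:4]) +
                      c(1, -1, 1, -1) / sqrt(2))
  expect_equal(negative_log_likelihood(p, 1, cv2), 2 * log(2 * pi) + 1)
  # the profiled variance is SSE / n
  nll_s2 <- function(s2) negative_log_likelihood(p, s2, cv2)
  opt <- optimize(nll_s2, c(1e-4, 10))
  sse <- sum((cv2$y - loglogistic_eval(p, cv2$x))^2)
  expect_equal(opt$minimum, sse / cv2$n, tolerance = 1e-4)
  expect_error(negative_log_likelihood(p, 0, cv), "positive")
})

test_that("MLE and OLS objectives agree at the optimum with equal weights", {
  set.seed(13)
  cv <- toy_curve(back = 0.4, sd = 0.05)
  ols <- fit_loglogistic(cv, objective = "OLS")
  mle <- fit_loglogistic(cv, objective = "MLE")
  expect_equal(mle$params, ols$params, tolerance = 1e-4)
  expect_equal(mle$sigma2_mle, mle$sse_m1 / cv$n, tolerance = 1e-4)
  expect_identical(ols$sigma2_mle, NA_real_)
})

test_that("fitting is deterministic: identical input gives identical output", {
  set.seed(14)
  cv <- toy_curve(sd = 0.05)
  f1 <- fit_loglogistic(cv)
  f2 <- fit_loglogistic(cv)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$sse_m1, f2$sse_m1)
})

test_that("multi-start fit reaches the global minimum on synthetic truth", {
  # module-scale version; the full 500-curve study runs with the
  # acceptance checks
  ds <- make_regulated_dataset(100, variance_source = 0.05, seed = 15)
  for (i in seq_along(ds$curves)) {
    cv <- ds$curves[[i]]
    fit <- fit_loglogistic(cv)
    tp <- c(pEC50 = ds$truth$pEC50[i], slope = ds$truth$slope[i],
            front = 1, back = ds$truth$back[i])
    sse_truth <- sum((cv$y - loglogistic_eval(tp, cv$x))^2)
    expect_lte(fit$sse_m1, sse_truth * (1 + 1e-6))
  }
})

test_that("independent Levenberg-Marquardt oracle finds no better optimum", {
  skip_if_not_installed("minpack.lm")
  set.seed(16)
  ds <- make_mixture_dataset(15, 0.5, seed = 16)
  for (cv in ds$curves) {
    fit <- fit_loglogistic(cv)
    b <- default_bounds(cv$x)
    best_oracle <- Inf
    for (s in list(fit$params * 0 + c(7, 1, 1, 0.5),
                   c(6, 0.8, quantile(cv$y, 0.9, names = FALSE),
                     quantile(cv$y, 0.1, names = FALSE)),
                   fit$params)) {
      o <- try(minpack.lm::nls.lm(
        par = pmin(pmax(s, b$lower), b$upper),
        lower = b$lower, upper = b$upper,
        fn = function(p) cv$y - loglogistic_eval(
          c(pEC50 = p[[1]], slope = p[[2]], front = p[[3]], back = p[[4]]),
          cv$x),
        control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
      if (!inherits(o, "try-error")) {
        best_oracle <- min(best_oracle, sum(o$fvec^2))
      }
    }
    expect_lte(fit$sse_m1, best_oracle * (1 + 1e-6) + 1e-12)
  }
})

test_that("fit_drc returns a complete model object with working methods", {
  set.seed(17)
  fit <- fit_drc(std_doses, loglogistic_eval(
    c(pEC50 = 7, slope = 1, front = 1, back = 0.3), std_doses) +
      rnorm(10, sd = 0.02), curve_id = "ex")
  expect_s3_class(fit, "drc_fit")
  expect_named(coef(fit), c("pEC50", "slope", "front", "back"))
  expect_equal(length(fitted(fit)), 10)
  expect_equal(residuals(fit), fit$curve$y - fitted(fit))
  expect_equal(predict(fit, newdata = -7),
               loglogistic_eval(coef(fit), -7))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(10, 3))
  s <- summary(fit)
  expect_s3_class(s, "summary.drc_fit")
  expect_true(s$p >= 0 && s$p <= 1)
  expect_output(print(fit), "fold change")
})
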