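test_that("s0 derives from the asymptotes via the central F quantile", {
  # zero fold-change asymptote disables the penalty entirely
  expect_equal(compute_s0(0.05, 0, 10), 0)
  expect_equal(compute_s0(0.37, 0, 23), 0)
  # closed form: fc / sqrt(qf(1 - alpha, 5, dfd))
  expect_equal(compute_s0(0.05, 0.45, 10),
               0.45 / sqrt(qf(0.95, 5, effective_dfd(10))))
  # monotone: larger fc asymptote, larger s0; stricter alpha, smaller s0
  expect_gt(compute_s0(0.05, 0.6, 10), compute_s0(0.05, 0.45, 10))
  expect_lt(compute_s0(0.01, 0.45, 10), compute_s0(0.05, 0.45, 10))
  # per-n values differ (missing values get their own boundary)
  expect_false(compute_s0(0.05, 0.45, 8) == compute_s0(0.05, 0.45, 10))
  expect_error(compute_s0(0, 0.3, 10), "alpha")
  expect_error(compute_s0(1.2, 0.3, 10), "alpha")
})

test_that("s0-adjusted F-value penalises small effect sizes", {
  # s0 = 0 leaves F unchanged
  expect_equal(adjusted_f(c(0.5, 4, 100), c(1, -0.2, 0.01), 0),
               c(0.5, 4, 100))
  # hand arithmetic: 1 / (1/2 + 0.214/0.45)^2
  expect_equal(adjusted_f(4, 0.45, 0.214), 1 / (0.5 + 0.214 / 0.45)^2,
               tolerance = 1e-12)
  expect_equal(adjusted_f(4, 0.45, 0.214), 1.0507, tolerance = 1e-4)
  # saturation: infinitely significant curves cap at (|cfc|/s0)^2
  expect_equal(adjusted_f(Inf, -0.6, 0.2), 9)
  # edge conventions
  expect_equal(adjusted_f(0, 0.5, 0.2), 0)
  expect_equal(adjusted_f(5, 0, 0.2), 0)
  # symmetric in the sign of the fold change
  expect_equal(adjusted_f(7, 0.8, 0.2), adjusted_f(7, -0.8, 0.2))
  # f_adj <= f whenever s0 > 0
  set.seed(21)
  f <- 10^runif(500, -2, 3)
  cfc <- runif(500, -3, 3)
  expect_true(all(adjusted_f(f, cfc, 0.2) <= f))
})

test_that("relevance score is the -log10 tail of the adjusted F", {
  # no evidence, no relevance
  expect_equal(relevance_score(0, 10), 0)
  expect_equal(relevance_score(0.12, 10), 0)
  # with s0 = 0 the score is exactly -log10(p)
  f <- c(0.05, 0.7, 2.5, 30)
  expect_equal(relevance_score(adjusted_f(f, 1.3, 0), 10),
               -log10(p_value(f, 10)))
  # frozen quadrature oracle at f_adj = 2.5, n = 10
  expect_equal(relevance_score(2.5, 10), 0.79168028, tolerance = 1e-6)
  # monotone in f_adj
  s <- relevance_score(seq(0, 50, by = 0.1), 10)
  expect_true(all(diff(s) >= 0))
})

test_that("penalty grows with decreasing effect size at fixed significance", {
  n <- 10
  s0 <- compute_s0(0.05, 0.45, n)
  cfc <- seq(0.05, 3, by = 0.05)
  for (f in c(2, 10, 80)) {
    rel <- relevance_score(adjusted_f(f, cfc, s0), n)
    expect_true(all(diff(rel) >= 0))
  }
})

test_that("explicit hyperbola and relevance threshold are the same rule", {
  set.seed(22)
  n <- 10
  for (fc_lim in c(0, 0.3)) {
    b <- drc_boundary(alpha = 0.05, fc_lim = fc_lim)
    s0 <- compute_s0(b$alpha, b$fc_lim, n)
    f <- 10^runif(2000, -2, 3)
    cfc <- runif(2000, -3, 3)
    by_rel <- relevance_score(adjusted_f(f, cfc, s0), n) >= -log10(b$alpha)
    by_hyp <- hyperbolic_boundary_test(f, cfc, b, n)
    expect_identical(by_rel, by_hyp)
    if (fc_lim > 0) expect_false(any(by_rel[abs(cfc) < fc_lim]))
  }
  # perfect fits: regulated iff the effect clears the asymptote
  b <- drc_boundary(alpha = 0.05, fc_lim = 0.3)
  expect_true(hyperbolic_boundary_test(Inf, 1, b, 10))
  expect_false(hyperbolic_boundary_test(Inf, 0.1, b, 10))
})

test_that("classification separates up, down, not and unclear", {
  b <- drc_boundary(alpha = 0.05, fc_lim = 0.4, rmse_limit = 0.1)
  thr <- -log10(b$alpha)
  # clearly regulated, sign from the fold change
  expect_equal(classify_curves(thr + 1, -1, 1.2, 0.3, boundary = b), "down")
  expect_equal(classify_curves(thr + 1, 0.8, 0.8, 0.3, boundary = b), "up")
  # confident flat: intercept near 1, low variance
  expect_equal(classify_curves(0.2, 0.05, 1.0, 0.05, boundary = b), "not")
  # high variance, not significant: unclear
  expect_equal(classify_curves(0.2, 0.05, 1.0, 0.3, boundary = b), "unclear")
  # intercept too far from 1 for a confident negative
  expect_equal(classify_curves(0.2, 0.05, 1.5, 0.05, boundary = b), "unclear")
  # optional p-value criterion tightens the negative class
  b2 <- drc_boundary(alpha = 0.05, fc_lim = 0.4, not_p_min = 0.5)
  expect_equal(classify_curves(0.2, 0.05, 1.0, 0.05, p = 0.1, boundary = b2),
               "unclear")
  expect_equal(classify_curves(0.2, 0.05, 1.0, 0.05, p = 0.9, boundary = b2),
               "not")
  # single-curve wrapper agrees
  stats <- list(relevance = thr + 1, cfc = -1, p = 0.001)
  fit <- list(mean_fit = list(intercept = 1.2), rmse_m0 = 0.3)
  expect_equal(classify_curve(stats, fit, b), "down")
})

test_that("regulated set size responds smoothly to the fc asymptote", {
  cfg0 <- drc_config(doses = 10^std_doses, alpha = 0.05, fc_lim = 0.3)
  ds <- make_mixture_dataset(1500, 0.15, seed = 23)
  scr <- run_pipeline(cfg0, ds)
  res <- scr$results
  counts <- vapply(c(0.25, 0.30, 0.35), function(fc) {
    b <- drc_boundary(alpha = 0.05, fc_lim = fc)
    s0 <- compute_s0(b$alpha, b$fc_lim, res$n, b$calib)
    rel <- relevance_score(adjusted_f(res$f_value, res$cfc, s0), res$n)
    sum(rel >= -log10(b$alpha) & res$cfc != 0)
  }, numeric(1))
  ref <- counts[2]
  expect_gt(ref, 0)
  expect_lt(abs(counts[1] - ref), 0.1 * ref + 1)
  expect_lt(abs(counts[3] - ref), 0.1 * ref + 1)
  # wider asymptote never admits more curves
  expect_true(all(diff(counts) <= 0))
})
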