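test_that("generators are reproducible from the seed", {
  for (gen in list(function(s) make_null_dataset(20, seed = s),
                   function(s) make_regulated_dataset(20, seed = s),
                   function(s) make_mixture_dataset(20, 0.5, seed = s))) {
    a <- gen(7)
    b <- gen(7)
    expect_identical(lapply(a$curves, `[[`, "y"), lapply(b$curves, `[[`, "y"))
    expect_identical(a$truth, b$truth)
  }
})

test_that("null datasets are flat in truth with the drawn noise", {
  ds <- make_null_dataset(500, seed = 8)
  expect_true(all(ds$truth$label == "null"))
  ybar <- mean(vapply(ds$curves, function(cv) mean(cv$y), 0))
  expect_lt(abs(ybar - 1), 0.01)
  # pooled standardized squared residuals behave like chi-square draws
  z2 <- unlist(lapply(seq_along(ds$curves), function(i) {
    (ds$curves[[i]]$y - 1)^2 / ds$truth$sigma[i]^2
  }))
  expect_lt(abs(mean(z2) - 1), 3 * sqrt(2 / length(z2)) + 0.05)
  # stand-in sigmas respect the truncation range
  expect_true(all(ds$truth$sigma >= 0.005 & ds$truth$sigma <= 0.5))
})

test_that("noiseless regulated curves recover the generating truth", {
  ds <- make_regulated_dataset(10, variance_source = 0, seed = 9)
  for (i in 1:10) {
    fit <- fit_loglogistic(ds$curves[[i]])
    expect_lt(abs(fit$params[["pEC50"]] - ds$truth$pEC50[i]), 1e-3)
    expect_lt(abs(fit$params[["back"]] - ds$truth$back[i]), 1e-4)
  }
})

test_that("regulated curves at assay-like noise are detected as regulated", {
  # truth |cfc| = 1 down-regulations, sigma = 0.05, n = 10
  cfg <- drc_config(doses = 10^std_doses, alpha = 0.05, fc_lim = 0.45)
  ds <- make_regulated_dataset(200, variance_source = 0.05,
                               cfc_range = c(1, 1), sign = "down", seed = 10)
  scr <- run_pipeline(cfg, ds)
  expect_gte(mean(scr$results$label == "down"), 0.95)
})

test_that("a truth EC50 far outside the dose range compresses the fold change", {
  # the curve barely starts inside the observed window, so the fitted
  # effect size underestimates the saturated truth
  pars <- c(pEC50 = -max(std_doses) - 3, slope = 1, front = 1, back = 0.5)
  cv <- curve_data(std_doses, loglogistic_eval(pars, std_doses))
  fit <- fit_drc(cv)
  expect_lt(abs(fit$stats$cfc), 0.5 * 1)  # truth saturated |cfc| = 1
})

test_that("mixture composition and edge fractions behave as specified", {
  ds <- make_mixture_dataset(40, 0.25, seed = 11)
  expect_equal(nrow(ds$truth), 40)
  expect_equal(sum(ds$truth$label != "null"), 10)
  expect_setequal(vapply(ds$curves, `[[`, "", "curve_id"), ds$truth$curve_id)
  # fraction 0 reduces to the null generator (up to shuffling)
  m0 <- make_mixture_dataset(15, 0, seed = 12)
  n0 <- make_null_dataset(15, seed = 12)
  expect_setequal(vapply(m0$curves, `[[`, "", "curve_id"),
                  vapply(n0$curves, `[[`, "", "curve_id"))
  y_m <- lapply(m0$curves, `[[`, "y")
  names(y_m) <- vapply(m0$curves, `[[`, "", "curve_id")
  y_n <- lapply(n0$curves, `[[`, "y")
  names(y_n) <- vapply(n0$curves, `[[`, "", "curve_id")
  expect_identical(y_m[sort(names(y_m))], y_n[sort(names(y_n))])
  # fraction 1 reduces to the regulated generator
  m1 <- make_mixture_dataset(15, 1, seed = 13)
  expect_true(all(m1$truth$label %in% c("up", "down")))
  expect_error(make_mixture_dataset(10, 1.5, seed = 1))
})

test_that("pEC50 recovery meets the screening-grade bar at sigma 0.05", {
  ds <- make_regulated_dataset(100, variance_source = 0.05,
                               cfc_range = c(1, 1), seed = 14)
  pe <- vapply(seq_along(ds$curves), function(i) {
    fit_loglogistic(ds$curves[[i]])$params[["pEC50"]]
  }, 0)
  expect_gte(mean(abs(pe - ds$truth$pEC50) <= 0.3), 0.9)
})

test_that("fixtures round-trip through the canonical file dialect", {
  ds <- make_mixture_dataset(12, 0.5, seed = 15)
  dir <- tempfile()
  paths <- write_fixture(ds, dir)
  expect_true(file.exists(paths[["data"]]))
  expect_true(file.exists(paths[["truth"]]))
  cfg <- drc_config(doses = 10^std_doses)
  rd <- read_curve_table(paths[["data"]], cfg)
  expect_equal(length(rd$curves), 12)
  # responses survive the round trip
  ids <- vapply(rd$curves, `[[`, "", "curve_id")
  i <- match(ds$curves[[1]]$curve_id, ids)
  expect_equal(rd$curves[[i]]$y, ds$curves[[1]]$y, tolerance = 1e-6)
})
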