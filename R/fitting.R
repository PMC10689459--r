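#' Control settings for curve fitting
#'
#' @param tol Convergence tolerance on the objective (default 1e-10).
#' @param maxit Maximum iterations per start (default 500).
#' @param min_n Minimum usable data points required to attempt a fit
#'   (default 5; a 4-parameter model needs at least k + 1 points).
#' @return A list of control settings.
#' @export
fit_control <- function(tol = 1e-10, maxit = 500, min_n = 5) {
  stopifnot(tol > 0, maxit >= 1, min_n >= 1)
  list(tol = tol, maxit = maxit, min_n = min_n)
}

#' Parameter bounds for the log-logistic fit
#'
#' pEC50 is constrained to the experimental log-dose range extended by 4
#' orders of magnitude on either side; slope to \[0.01, 20\]; the two
#' plateaus to \[1e-3, 1e6\].
#'
#' @param x Log10 doses of the curve (the experimental range).
#' @return List with `lower` and `upper` named numeric vectors over
#'   (pEC50, slope, front, back).
#' @export
default_bounds <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite doses to derive bounds from")
  list(
    lower = c(pEC50 = -max(x) - 4, slope = 0.01, front = 1e-3, back = 1e-3),
    upper = c(pEC50 = -min(x) + 4, slope = 20, front = 1e6, back = 1e6)
  )
}

#' Deterministic multi-start grid for the log-logistic fit
#'
#' Candidate starting points: pEC50 at 7 equally spaced positions across the
#' experimental dose range, slope in \{0.5, 1, 2\}, and front/back taken from
#' the 10th/90th percentiles of the responses in both orientations
#' (decreasing and increasing curves). Duplicate rows are removed, so a
#' curve with distinct percentiles yields 7 x 3 x 2 = 42 starts.
#'
#' @param curve A [curve_data()] object.
#' @param bounds Parameter bounds as from [default_bounds()]; starts are
#'   clamped into them.
#' @return Numeric matrix with columns `pEC50`, `slope`, `front`, `back`,
#'   one row per start.
#' @export
build_start_grid <- function(curve, bounds = default_bounds(curve$x)) {
  stopifnot_curve(curve)
  if (curve$n == 0) stop("cannot build a start grid for an empty curve")
  xr <- range(curve$x)
  pec50 <- if (xr[1] == xr[2]) -xr[1] else seq(-xr[2], -xr[1], length.out = 7)
  slopes <- c(0.5, 1, 2)
  qs <- quantile(curve$y, c(0.1, 0.9), names = FALSE, type = 7)
  fb <- if (qs[1] == qs[2]) matrix(qs[1], 1, 2) else {
    rbind(c(qs[2], qs[1]), c(qs[1], qs[2]))  # decreasing, increasing
  }
  np <- length(pec50); ns <- length(slopes); nf <- nrow(fb)
  starts <- cbind(pEC50 = rep(pec50, times = ns * nf),
                  slope = rep(rep(slopes, each = np), times = nf),
                  front = rep(fb[, 1], each = np * ns),
                  back = rep(fb[, 2], each = np * ns))
  clamped <- FALSE
  for (j in 1:4) {
    cl <- pmin(pmax(starts[, j], bounds$lower[j]), bounds$upper[j])
    if (!identical(cl, unname(starts[, j]))) clamped <- TRUE
    starts[, j] <- cl
  }
  if (clamped) starts <- starts[!duplicated(starts), , drop = FALSE]
  starts
}

#' Gaussian negative log-likelihood of the log-logistic model
#'
#' \eqn{-\sum \ln L = n/2 \ln(2\pi\sigma^2) + SSE/(2\sigma^2)} with the
#' weighted SSE of the residuals. At fixed parameters the minimizing
#' variance is `SSE / n`, so the profiled likelihood optimum coincides with
#' the least-squares optimum when weights are equal.
#'
#' @inheritParams loglogistic_eval
#' @param sigma2 Error variance, must be positive.
#' @param curve A [curve_data()] object.
#' @return Scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(params, sigma2, curve) {
  stopifnot_curve(curve)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  r <- curve$y - loglogistic_eval(params, curve$x)
  sse <- sum(curve$w * r^2)
  curve$n / 2 * log(2 * pi * sigma2) + sse / (2 * sigma2)
}

#' Fit the log-logistic model to one curve
#'
#' Bounded multi-start minimisation: every start from [build_start_grid()]
#' (or user-supplied starts) is optimised with L-BFGS-B using analytic
#' gradients, and the lowest-objective solution is returned. The constant
#' curve lies in the closure of the model family (front = back), so the
#' returned SSE never exceeds the mean-model SSE: if no start beats the
#' mean model, the flat solution is reported. With `objective = "MLE"` the
#' OLS solution seeds a joint Nelder-Mead minimisation of the Gaussian
#' negative log-likelihood over the four curve parameters and the error
#' variance.
#'
#' @param curve A [curve_data()] object.
#' @param bounds Parameter bounds; default [default_bounds()] on the
#'   curve's doses.
#' @param objective `"OLS"` (default) or `"MLE"`.
#' @param starts Optional start matrix; default [build_start_grid()].
#' @param control See [fit_control()].
#' @return A `fit_bundle` list: `params` (named vector), `sse_m1`,
#'   `mean_fit`, `sse_m0`, `rmse_m0`, `n`, `converged`, `n_starts_used`,
#'   `objective`, `sigma2_mle` (NA for OLS).
#'
#' @examples
#' x <- seq(-9, -5, length.out = 10)
#' y <- loglogistic_eval(c(pEC50 = 7, slope = 1, front = 1, back = 0.3), x)
#' fit_loglogistic(curve_data(x, y))$params
#' @export
fit_loglogistic <- function(curve, bounds = default_bounds(curve$x),
                            objective = c("OLS", "MLE"), starts = NULL,
                            control = fit_control()) {
  stopifnot_curve(curve)
  objective <- match.arg(objective)
  if (curve$n < control$min_n) {
    stop("curve '", curve$curve_id, "' has ", curve$n,
         " usable points; minimum is ", control$min_n)
  }
  mf <- mean_model_fit(curve)
  if (is.null(starts)) starts <- build_start_grid(curve, bounds)

  # Fit on standardized responses (centered at the mean-model intercept,
  # scaled by its RMSE). This conditions the optimization independently of
  # the data's intensity scale, and makes the resulting F-statistic exactly
  # invariant to rescaling the residual noise: the standardized problem is
  # the same. Plateau parameters and SSEs are mapped back afterwards.
  ctr <- mf$intercept
  scl <- if (mf$rmse > 0) mf$rmse else 1
  y_t <- (curve$y - ctr) / scl
  starts_t <- starts
  starts_t[, c("front", "back")] <- (starts[, c("front", "back")] - ctr) / scl
  lower_t <- bounds$lower
  upper_t <- bounds$upper
  lower_t[c("front", "back")] <- (bounds$lower[c("front", "back")] - ctr) / scl
  upper_t[c("front", "back")] <- (bounds$upper[c("front", "back")] - ctr) / scl

  factr <- control$tol / .Machine$double.eps
  res <- cc_fit_ols(curve$x, y_t, curve$w, starts_t,
                    lower_t, upper_t,
                    factr, 0.0, as.integer(control$maxit))
  params <- res$par
  params[c("front", "back")] <- ctr + scl * params[c("front", "back")]
  sse_m1 <- res$sse * scl^2
  converged <- isTRUE(res$converged) && all(is.finite(params))

  # flat-curve fallback: the mean model is inside the family closure
  if (!all(is.finite(params)) || sse_m1 > mf$sse * (1 + 1e-9) + 1e-12) {
    flat <- pmin(pmax(mf$intercept, bounds$lower[["front"]]),
                 bounds$upper[["front"]])
    params <- c(pEC50 = mean(-range(curve$x)), slope = 1,
                front = flat, back = flat)
    sse_m1 <- cc_sse_loglogistic(curve$x, curve$y, curve$w, params)
    converged <- FALSE
  }
  sse_m1 <- min(sse_m1, mf$sse)

  sigma2_mle <- NA_real_
  if (objective == "MLE") {
    mle <- mle_polish(curve, params, sse_m1, bounds, control)
    params <- mle$params
    sigma2_mle <- mle$sigma2
    r <- curve$y - loglogistic_eval(params, curve$x)
    sse_m1 <- min(sum(curve$w * r^2), mf$sse)
    converged <- converged && mle$converged
  }

  structure(list(params = params, sse_m1 = sse_m1, mean_fit = mf,
                 sse_m0 = mf$sse, rmse_m0 = mf$rmse, n = curve$n,
                 converged = converged, n_starts_used = nrow(starts),
                 objective = objective, sigma2_mle = sigma2_mle),
            class = "fit_bundle")
}

# Nelder-Mead joint minimisation of the negative log-likelihood over
# (theta, log sigma2), seeded at the OLS solution; bounds enforced by an
# infinite penalty outside the box.
mle_polish <- function(curve, params, sse_ols, bounds, control) {
  s2_0 <- max(sse_ols / curve$n, 1e-12)
  par0 <- c(params, log_s2 = log(s2_0))
  nll <- function(p) {
    th <- p[1:4]
    if (any(th < bounds$lower) || any(th > bounds$upper)) return(1e300)
    negative_log_likelihood(stats::setNames(th, names(params)), exp(p[5]), curve)
  }
  opt <- optim(par0, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = control$tol))
  list(params = stats::setNames(opt$par[1:4], names(params)),
       sigma2 = unname(exp(opt$par[5])),
       converged = opt$convergence == 0)
}

#' @export
print.fit_bundle <- function(x, ...) {
  cat("<fit_bundle> n =", x$n, " objective =", x$objective,
      if (!x$converged) "(not converged)", "\n")
  print(signif(x$params, 6))
  cat("SSE(M1) =", format(x$sse_m1, digits = 6),
      " SSE(M0) =", format(x$sse_m0, digits = 6), "\n")
  invisible(x)
}

#' Fit and test a single dose-response curve
#'
#' The modelling front end: fits the 4-parameter log-logistic model to one
#' curve, computes the recalibrated F-statistic, its calibrated p-value, and
#' the curve fold change, and returns a classed object with the usual
#' accessor methods (`print`, `summary`, `coef`, `predict`, `fitted`,
#' `residuals`, `simulate`, `plot`).
#'
#' @param x Log10 molar doses, or a [curve_data()] object (then `y` is
#'   ignored).
#' @param y Responses (ratio to control).
#' @param w Optional weights.
#' @param curve_id Curve identifier.
#' @param objective `"OLS"` or `"MLE"`.
#' @param fc_mode Fold-change mode, see [fold_change()].
#' @param calib F-statistic calibration, see [f_calibration()].
#' @param control See [fit_control()].
#' @return An object of class `drc_fit`.
#'
#' @examples
#' x <- seq(-9, -5, length.out = 10)
#' y <- loglogistic_eval(c(pEC50 = 7, slope = 1, front = 1, back = 0.3), x) +
#'   rnorm(10, sd = 0.03)
#' fit <- fit_drc(x, y)
#' coef(fit)
#' summary(fit)
#' @export
fit_drc <- function(x, y = NULL, w = NULL, curve_id = "curve",
                    objective = c("OLS", "MLE"),
                    fc_mode = c("range", "control"),
                    calib = f_calibration(), control = fit_control()) {
  curve <- if (inherits(x, "curve_data")) x else curve_data(x, y, w, curve_id)
  objective <- match.arg(objective)
  fc_mode <- match.arg(fc_mode)
  fit <- fit_loglogistic(curve, objective = objective, control = control)
  stats <- curve_statistics(fit, curve, calib = calib, fc_mode = fc_mode)
  structure(list(curve = curve, fit = fit, stats = stats, calib = calib,
                 call = match.call()),
            class = "drc_fit")
}

# F, dfd, p and fold change for one fitted curve
curve_statistics <- function(fit, curve, calib = f_calibration(),
                             fc_mode = "range") {
  f <- f_value(fit$sse_m0, fit$sse_m1, fit$n, k = calib$k)
  cfc <- fold_change(fit$params, min(curve$x), max(curve$x), mode = fc_mode)
  list(f = f, dfd = effective_dfd(fit$n), p = p_value(f, fit$n, calib),
       cfc = cfc)
}

#' @export
coef.drc_fit <- function(object, ...) object$fit$params

#' @export
fitted.drc_fit <- function(object, ...) {
  loglogistic_eval(object$fit$params, object$curve$x)
}

#' @export
residuals.drc_fit <- function(object, ...) {
  object$curve$y - fitted(object)
}

#' @export
predict.drc_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$x else {
    if (is.list(newdata)) newdata$x else newdata
  }
  loglogistic_eval(object$fit$params, x)
}

#' @export
simulate.drc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  n <- length(mu)
  s2 <- if (is.finite(object$fit$sigma2_mle)) object$fit$sigma2_mle
        else object$fit$sse_m1 / max(object$fit$n - object$calib$k, 1)
  out <- as.data.frame(replicate(nsim, mu + rnorm(n, sd = sqrt(s2))))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.drc_fit <- function(x, ...) {
  cat("Log-logistic dose-response fit:", x$curve$curve_id, "\n")
  print(signif(coef(x), 6))
  cat(sprintf("n = %d, F = %.4g, p = %.4g, log2 fold change = %.4g\n",
              x$fit$n, x$stats$f, x$stats$p, x$stats$cfc))
  invisible(x)
}

#' @export
summary.drc_fit <- function(object, ...) {
  out <- list(curve_id = object$curve$curve_id,
              params = coef(object),
              n = object$fit$n,
              sse_m0 = object$fit$sse_m0, sse_m1 = object$fit$sse_m1,
              rmse_m0 = object$fit$rmse_m0,
              intercept = object$fit$mean_fit$intercept,
              f = object$stats$f, dfd = object$stats$dfd,
              p = object$stats$p, cfc = object$stats$cfc,
              converged = object$fit$converged)
  class(out) <- "summary.drc_fit"
  out
}

#' @export
print.summary.drc_fit <- function(x, ...) {
  cat("Curve:", x$curve_id, " (n =", x$n, ")\n")
  cat("Parameters:\n")
  print(signif(x$params, 6))
  cat(sprintf("EC50 = %.3g M\n", 10^(-x$params[["pEC50"]])))
  cat(sprintf("SSE mean model     = %.6g (RMSE %.4g, intercept %.4g)\n",
              x$sse_m0, x$rmse_m0, x$intercept))
  cat(sprintf("SSE logistic model = %.6g\n", x$sse_m1))
  cat(sprintf("Recalibrated F = %.4g on (5, %.4g) effective df, p = %.4g\n",
              x$f, x$dfd, x$p))
  cat(sprintf("Curve log2 fold change = %.4g\n", x$cfc))
  if (!x$converged) cat("Warning: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
plot.drc_fit <- function(x, n_grid = 200, ...) {
  cv <- x$curve
  xg <- seq(min(cv$x), max(cv$x), length.out = n_grid)
  plot(cv$x, cv$y, xlab = "log10 dose [M]", ylab = "response (ratio)",
       main = cv$curve_id, ...)
  lines(xg, loglogistic_eval(x$fit$params, xg), col = "firebrick", lwd = 2)
  abline(h = x$fit$mean_fit$intercept, col = "grey50", lty = 2)
  invisible(x)
}
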