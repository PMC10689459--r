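#' Decision boundary combining significance and effect size
#'
#' A boundary is defined by two asymptotes: the significance asymptote
#' `alpha` (no curve with p-value above `alpha` is ever called regulated,
#' however large its effect) and the fold-change asymptote `fc_lim` (no
#' curve with |log2 fold change| below `fc_lim` is ever called regulated,
#' however significant). The two asymptotes define a hyperbola in the
#' volcano plot, parameterised by the tuning constant s0 derived with
#' [compute_s0()]; s0 depends on the curve's number of data points, so each
#' n gets its own value.
#'
#' @param alpha Significance asymptote in (0, 1); default 0.05.
#' @param fc_lim Fold-change asymptote in log2 units, >= 0.
#' @param rmse_limit Maximum mean-model RMSE for the "not" (clearly flat)
#'   class; default 0.1.
#' @param not_p_min Optional extra criterion for the "not" class: require
#'   p >= `not_p_min` (default `NULL`, disabled).
#' @param intercept_space `"log2"` (default) or `"linear"`: how "intercept
#'   within fc_lim/2 of 1" is measured for the "not" class.
#' @param calib Calibration constants, see [f_calibration()].
#' @param s0_use_loc If `TRUE`, include the location shift in the quantile
#'   used by [compute_s0()] (default `FALSE`, the printed form).
#' @return A list of class `drc_boundary`.
#' @export
drc_boundary <- function(alpha = 0.05, fc_lim = 0.45, rmse_limit = 0.1,
                         not_p_min = NULL, intercept_space = c("log2", "linear"),
                         calib = f_calibration(), s0_use_loc = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (!is.finite(fc_lim) || fc_lim < 0) stop("fc_lim must be >= 0")
  structure(list(alpha = alpha, fc_lim = fc_lim, rmse_limit = rmse_limit,
                 not_p_min = not_p_min,
                 intercept_space = match.arg(intercept_space),
                 calib = calib, s0_use_loc = s0_use_loc),
            class = "drc_boundary")
}

#' @export
print.drc_boundary <- function(x, ...) {
  cat(sprintf("<drc_boundary> alpha = %g, fc_lim = %g (s0 at n=10: %.4g)\n",
              x$alpha, x$fc_lim,
              compute_s0(x$alpha, x$fc_lim, 10, x$calib, x$s0_use_loc)))
  invisible(x)
}

#' s0 tuning parameter from the boundary asymptotes
#'
#' `s0 = fc_asymptote / sqrt(Q)` where `Q` is the `(1 - alpha)` quantile of
#' the central F-distribution with `dfn` and the effective `dfd(n)`. s0
#' converts the two user-facing asymptotes into the single constant that
#' bends the decision boundary into a hyperbola. Because dfd depends on the
#' curve's number of points, s0 is a function of n, which matters for
#' curves with missing values.
#'
#' The quantile is central (no location shift) by default, which reproduces
#' the conventional printed s0 values; set `use_loc = TRUE` to include the
#' shift of the calibrated null distribution instead (the two conventions
#' differ in the third decimal).
#'
#' @param alpha Significance asymptote in (0, 1).
#' @param fc_asymptote Fold-change asymptote (log2 units, >= 0).
#' @param n Number of data points (>= 4); vectorised.
#' @param calib See [f_calibration()].
#' @param use_loc Include the location shift in the quantile (default
#'   `FALSE`).
#' @return s0 >= 0 (0 iff `fc_asymptote` = 0).
#' @examples
#' compute_s0(0.01, 0.3, 17)   # ~0.13
#' compute_s0(0.05, 0.45, 10)  # ~0.214
#' @export
compute_s0 <- function(alpha, fc_asymptote, n, calib = f_calibration(),
                       use_loc = FALSE) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  if (fc_asymptote < 0) stop("fc_asymptote must be >= 0")
  if (fc_asymptote == 0) return(rep(0, length(n)))
  q <- qf(1 - alpha, calib$dfn, effective_dfd(n)) * calib$scale
  if (use_loc) q <- q + calib$loc
  fc_asymptote / sqrt(q)
}

#' s0-adjusted F-value
#'
#' `F_adj = 1 / (1/sqrt(F) + s0/|cfc|)^2`: the recalibrated F-value shrunk
#' according to the curve's effect size. Curves with small fold changes are
#' penalised strongly; as F grows, `F_adj` saturates at `(|cfc|/s0)^2`, so
#' no amount of significance can compensate for an effect size below the
#' asymptote. With `s0 = 0` the F-value is returned unchanged.
#'
#' @param f Recalibrated F-value(s), >= 0 (may be `Inf` for perfect fits).
#' @param cfc Curve log2 fold change(s); the absolute value enters the
#'   penalty so up- and down-regulations are treated symmetrically.
#' @param s0 Tuning parameter from [compute_s0()], >= 0.
#' @return Adjusted F-value(s); 0 when `f = 0` or when `cfc = 0` with
#'   `s0 > 0` (continuity convention).
#' @export
adjusted_f <- function(f, cfc, s0) {
  if (any(f < 0, na.rm = TRUE)) stop("F-values must be non-negative")
  if (any(s0 < 0)) stop("s0 must be non-negative")
  n_out <- max(length(f), length(cfc), length(s0))
  f <- rep_len(f, n_out); cfc <- rep_len(cfc, n_out); s0 <- rep_len(s0, n_out)
  out <- 1 / (1 / sqrt(f) + s0 / abs(cfc))^2
  out[s0 == 0] <- f[s0 == 0]
  out[f == 0] <- 0
  out[cfc == 0 & s0 > 0] <- 0
  out[is.infinite(f) & s0 > 0] <- (abs(cfc) / s0)[is.infinite(f) & s0 > 0]^2
  out
}

#' Relevance score
#'
#' `-log10` of the upper-tail probability of the s0-adjusted F-value under
#' the calibrated null distribution for a curve with n points. With
#' `s0 = 0` this is exactly `-log10(p)` of the curve; with `s0 > 0` it is
#' no longer a p-value but an ordering that blends statistical significance
#' with effect size. The score is 0 for curves with no evidence and grows
#' without bound.
#'
#' @param f_adj Adjusted F-value(s) from [adjusted_f()].
#' @param n Number of data points (recycled).
#' @param calib See [f_calibration()].
#' @return Relevance score(s) >= 0.
#' @export
relevance_score <- function(f_adj, n, calib = f_calibration()) {
  if (any(f_adj < 0, na.rm = TRUE)) stop("adjusted F-values must be >= 0")
  -p_value(f_adj, n, calib, log10p = TRUE)
}

#' Explicit hyperbolic decision boundary test
#'
#' The volcano-plot form of the regulation call: a curve with recalibrated
#' F-value `f` and log2 fold change `cfc` is called regulated iff its
#' effect size clears the fold-change asymptote and its F-value lies above
#' the hyperbola
#' \deqn{F \ge 1 / (1/\sqrt{Q^*} - s_0/|cfc|)^2,}
#' where `Q*` is the significance cutoff of the adjusted F (shifted
#' quantile) and s0 is derived from the boundary asymptotes. Exactly
#' equivalent to thresholding the relevance score at `-log10(alpha)`.
#'
#' @param f Recalibrated F-value(s).
#' @param cfc Curve log2 fold change(s).
#' @param boundary A [drc_boundary()].
#' @param n Number of data points (recycled).
#' @return Logical: does the curve lie beyond the decision boundary?
#' @export
hyperbolic_boundary_test <- function(f, cfc, boundary, n) {
  stopifnot(inherits(boundary, "drc_boundary"))
  calib <- boundary$calib
  n_out <- max(length(f), length(cfc), length(n))
  f <- rep_len(f, n_out); cfc <- rep_len(cfc, n_out); n <- rep_len(n, n_out)
  q_star <- qf(1 - boundary$alpha, calib$dfn, effective_dfd(n)) * calib$scale +
    calib$loc
  s0 <- compute_s0(boundary$alpha, boundary$fc_lim, n, calib,
                   boundary$s0_use_loc)
  inv_rad <- 1 / sqrt(q_star) - s0 / abs(cfc)
  # effect size must clear the |cfc| asymptote s0 * sqrt(q_star)
  ok_fc <- inv_rad > 0
  ok_fc & (is.infinite(f) | (f > 0 & 1 / sqrt(f) <= inv_rad))
}

#' Classify a curve as up-, down-, not regulated, or unclear
#'
#' A curve is `"up"` or `"down"` if its relevance score reaches
#' `-log10(alpha)` (sign from the fold change). A non-regulated curve is
#' `"not"` only if it is confidently flat: mean-model intercept within
#' `fc_lim/2` of 1 (in log2 or linear space) and mean-model RMSE at most
#' `rmse_limit`, plus the optional p-value criterion. Everything else is
#' `"unclear"` -- typically high-variance curves that are neither clearly
#' regulated nor clearly flat.
#'
#' @param relevance Relevance score(s).
#' @param cfc Curve log2 fold change(s).
#' @param intercept Mean-model intercept(s) (ratio units).
#' @param rmse_m0 Mean-model RMSE(s).
#' @param p p-value(s); only used when `boundary$not_p_min` is set.
#' @param boundary A [drc_boundary()].
#' @return Character vector in `c("up", "down", "not", "unclear")`.
#' @export
classify_curves <- function(relevance, cfc, intercept, rmse_m0, p = NULL,
                            boundary = drc_boundary()) {
  stopifnot(inherits(boundary, "drc_boundary"))
  thr <- -log10(boundary$alpha)
  n_out <- max(length(relevance), length(cfc), length(intercept),
               length(rmse_m0))
  relevance <- rep_len(relevance, n_out); cfc <- rep_len(cfc, n_out)
  intercept <- rep_len(intercept, n_out); rmse_m0 <- rep_len(rmse_m0, n_out)
  regulated <- relevance >= thr & cfc != 0
  lab <- rep("unclear", n_out)
  lab[regulated & cfc > 0] <- "up"
  lab[regulated & cfc < 0] <- "down"
  flat_int <- if (boundary$intercept_space == "log2") {
    intercept > 0 & abs(log2(intercept)) <= boundary$fc_lim / 2
  } else {
    abs(intercept - 1) <= boundary$fc_lim / 2
  }
  flat <- !regulated & flat_int & rmse_m0 <= boundary$rmse_limit
  if (!is.null(boundary$not_p_min)) {
    if (is.null(p)) stop("boundary$not_p_min set but no p-values supplied")
    flat <- flat & rep_len(p, n_out) >= boundary$not_p_min
  }
  lab[flat] <- "not"
  lab
}

#' @rdname classify_curves
#' @param stats A list with elements `relevance`, `cfc`, `p` (as produced
#'   by the pipeline) for a single curve.
#' @param fit A `fit_bundle` for the same curve.
#' @export
classify_curve <- function(stats, fit, boundary = drc_boundary()) {
  classify_curves(stats$relevance, stats$cfc, fit$mean_fit$intercept,
                  fit$rmse_m0, p = stats$p, boundary = boundary)
}
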