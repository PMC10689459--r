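#' Four-parameter log-logistic dose-response model
#'
#' Evaluates the sigmoidal response at log10 dose `x`:
#' \deqn{\hat y(x) = back + \frac{front - back}{1 + 10^{slope\,(x + pEC50)}}}
#' The curve runs from the `front` plateau at low dose to the `back` plateau
#' at high dose, with inflection at `x = -pEC50` and steepness `slope`.
#' Potency is parameterised as pEC50 = -log10(EC50 in molar), so larger
#' pEC50 means a more potent compound.
#'
#' @param params Named numeric vector or list with `pEC50`, `slope`,
#'   `front`, `back`; all finite, `slope > 0`.
#' @param x Numeric vector of log10 molar concentrations.
#' @return Numeric vector of model responses, same length as `x`.
#'
#' @examples
#' loglogistic_eval(c(pEC50 = 7, slope = 1, front = 1, back = 0), x = -7)
#' @export
loglogistic_eval <- function(params, x) {
  p <- check_params(params)
  u <- p[["slope"]] * (x + p[["pEC50"]])
  s <- sigmoid10(u)
  p[["back"]] + (p[["front"]] - p[["back"]]) * s
}

# 1 / (1 + 10^u), overflow-safe
sigmoid10 <- function(u) {
  s <- numeric(length(u))
  hi <- u > 300
  lo <- u < -300
  mid <- !hi & !lo
  s[hi] <- 0
  s[lo] <- 1
  s[mid] <- 1 / (1 + 10^u[mid])
  s
}

check_params <- function(params) {
  p <- unlist(params)[c("pEC50", "slope", "front", "back")]
  if (anyNA(p) || any(!is.finite(p))) {
    stop("invalid log-logistic parameters: need finite pEC50, slope, front, back")
  }
  if (p[["slope"]] <= 0) stop("slope must be positive")
  p
}

#' Gradient of the log-logistic model
#'
#' Partial derivatives of the model response with respect to
#' (pEC50, slope, front, back), used as the analytic Jacobian during
#' least-squares minimisation.
#'
#' @inheritParams loglogistic_eval
#' @return A `length(x) x 4` matrix with columns `pEC50`, `slope`,
#'   `front`, `back`.
#' @export
loglogistic_gradient <- function(params, x) {
  p <- check_params(params)
  z <- x + p[["pEC50"]]
  s <- sigmoid10(p[["slope"]] * z)
  ss1 <- s * (1 - s)
  fb <- p[["front"]] - p[["back"]]
  ln10 <- log(10)
  cbind(pEC50 = -fb * ln10 * p[["slope"]] * ss1,
        slope = -fb * ln10 * z * ss1,
        front = s,
        back  = 1 - s)
}

#' Fit the constant (mean) null model to a curve
#'
#' The null model states that the response is independent of dose; its
#' weighted least-squares solution is the weighted mean of the responses.
#'
#' @param curve A [curve_data()] object with `n >= 1`.
#' @return List with `intercept` (weighted mean), `sse` (weighted sum of
#'   squared residuals) and `rmse` (`sqrt(sse / n)`).
#'
#' @examples
#' mean_model_fit(curve_data(x = 1:3, y = c(0.8, 1.0, 1.2)))
#' @export
mean_model_fit <- function(curve) {
  stopifnot_curve(curve)
  if (curve$n == 0) stop("cannot fit the mean model to an empty curve")
  m <- weighted.mean(curve$y, curve$w)
  sse <- sum(curve$w * (curve$y - m)^2)
  list(intercept = m, sse = sse, rmse = sqrt(sse / curve$n))
}

#' Curve fold change (effect size)
#'
#' The log2 ratio of the model-predicted response at the highest versus the
#' lowest dose of the fitted range; the curve's effect size. In `"control"`
#' mode the reference is the control response instead of the model value at
#' the lowest dose (useful when compounds already act at the lowest dose);
#' under ratio normalization the control response is 1.
#'
#' @inheritParams loglogistic_eval
#' @param x_min,x_max Log10 doses delimiting the evaluated range.
#' @param mode `"range"` (default) or `"control"`.
#' @param y_control Control reference response for `mode = "control"`.
#' @return Signed log2 fold change; negative for down-regulation.
#' @export
fold_change <- function(params, x_min, x_max, mode = c("range", "control"),
                        y_control = 1) {
  mode <- match.arg(mode)
  y_hi <- loglogistic_eval(params, x_max)
  y_lo <- if (mode == "range") loglogistic_eval(params, x_min) else y_control
  if (y_hi <= 0 || y_lo <= 0) {
    stop("fold change requires positive responses at both ends")
  }
  log2(y_hi) - log2(y_lo)
}
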