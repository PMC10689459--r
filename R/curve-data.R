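#' Construct a single dose-response curve
#'
#' Bundles one curve's log10 doses, responses and weights into a validated
#' `curve_data` object, the unit of work for fitting and significance
#' testing. Responses are expected as ratios to the control sample
#' (control ~ 1) but any finite values are accepted; missing pairs are
#' dropped and `n` records the number of usable points.
#'
#' @param x Numeric vector of log10 molar concentrations. A control
#'   (zero-dose) sample cannot sit on the log axis; place it at a pseudo
#'   log-dose below the lowest real dose (see [control_pseudo_dose()]).
#' @param y Numeric vector of responses, same length as `x`.
#' @param w Optional non-negative weights (default all 1).
#' @param curve_id Identifier carried through to results tables.
#'
#' @return An object of class `curve_data`: a list with elements `curve_id`,
#'   `x`, `y`, `w` (sorted by increasing `x`, missing pairs removed) and `n`.
#'
#' @examples
#' cd <- curve_data(x = seq(-9, -5), y = c(1.02, 0.98, 0.7, 0.4, 0.35))
#' cd$n
#' @export
curve_data <- function(x, y, w = NULL, curve_id = "curve") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length (curve '", curve_id, "')")
  }
  if (is.null(w)) w <- rep(1, length(x))
  w <- as.numeric(w)
  if (length(w) != length(x)) {
    stop("w must match x in length (curve '", curve_id, "')")
  }
  if (any(w < 0, na.rm = TRUE)) {
    stop("weights must be non-negative (curve '", curve_id, "')")
  }
  keep <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  ord <- order(x)
  out <- list(curve_id = as.character(curve_id)[1],
              x = x[ord], y = y[ord], w = w[ord],
              n = length(x))
  class(out) <- "curve_data"
  out
}

#' @export
print.curve_data <- function(x, ...) {
  cat("<curve_data> ", x$curve_id, ": n = ", x$n, sep = "")
  if (x$n > 0) {
    cat(", log10 dose range [", format(min(x$x), digits = 4), ", ",
        format(max(x$x), digits = 4), "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Pseudo log-dose for a zero-dose control sample
#'
#' A control measured at dose 0 has no position on a log-dose axis. It is
#' anchored `offset` decades below the lowest real dose so that it pins the
#' front plateau of the curve without distorting the experimental range.
#'
#' @param x_doses Log10 doses of the real (non-control) measurements.
#' @param offset Decades below the minimum real dose (default 2).
#' @return A single pseudo log10 dose.
#' @export
control_pseudo_dose <- function(x_doses, offset = 2) {
  x_doses <- x_doses[is.finite(x_doses)]
  if (!length(x_doses)) stop("no finite doses supplied")
  if (!is.finite(offset) || offset <= 0) stop("offset must be positive")
  min(x_doses) - offset
}

stopifnot_curve <- function(curve) {
  if (!inherits(curve, "curve_data")) stop("expected a 'curve_data' object")
  invisible(curve)
}
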