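#' Per-curve sample variances from fitted curves
#'
#' `s_i^2 = SSE_M1 / dfd(n_i)`: the residual variance of each fitted curve
#' using the effective degrees of freedom as divisor. The resulting sample
#' is the dataset's own noise distribution, from which decoy curves are
#' drawn. Curves with (numerically) zero residuals carry no variance
#' information and are excluded.
#'
#' @param fits List of `fit_bundle` objects (see [fit_loglogistic()]).
#' @param tol Residual SSE below which a curve counts as zero-residual.
#' @return Numeric vector of variances with attribute `"n_excluded"`.
#' @export
estimate_variances <- function(fits, tol = 1e-12) {
  sse <- vapply(fits, function(f) f$sse_m1, numeric(1))
  n <- vapply(fits, function(f) f$n, numeric(1))
  keep <- sse > tol
  v <- sse[keep] / effective_dfd(n[keep])
  if (!length(v)) stop("no curves with non-zero residuals; cannot estimate variances")
  attr(v, "n_excluded") <- sum(!keep)
  v
}

#' Generate decoy curves from a variance sample
#'
#' Decoys are flat-truth curves `y = 1 + e`, `e ~ N(0, s_i^2)` with each
#' curve's variance resampled with replacement from the dataset's own
#' variance sample. Run through the identical fitting and scoring pipeline,
#' their scores estimate how often the analysis calls an unregulated curve
#' regulated.
#'
#' @param variance_sample Positive variances, e.g. from
#'   [estimate_variances()].
#' @param doses Log10 doses for the decoy curves.
#' @param n_decoys Number of decoys (default: size of the variance sample;
#'   a warning is given below 100, where q-values become unstable).
#' @param seed Integer seed.
#' @return List of [curve_data()] objects with ids `decoy_*` and attribute
#'   `"sigma"`.
#' @export
generate_decoys <- function(variance_sample, doses,
                            n_decoys = length(variance_sample), seed) {
  v <- as.numeric(variance_sample)
  v <- v[is.finite(v) & v > 0]
  if (!length(v)) stop("empty variance sample")
  if (n_decoys < 100) {
    warning("fewer than 100 decoys; q-value estimates will be unstable")
  }
  if (!missing(seed)) set.seed(seed)
  curves <- simulate_null_curves(n_decoys, doses, variance_source = v)
  for (i in seq_along(curves)) {
    curves[[i]]$curve_id <- sprintf("decoy_%06d", i)
  }
  curves
}

#' Target-decoy q-values from relevance scores
#'
#' For each target score `s`, the raw FDR at threshold `s` is
#' `#\{decoys >= s\} * (N_targets / N_decoys) / #\{targets >= s\}` (counting
#' inclusive of the curve itself, decoy counts rescaled when the decoy set
#' size differs from the target set). The q-value of a curve is the minimum
#' raw FDR over all thresholds at or below its score, clipped to \[0, 1\],
#' which makes q monotone non-increasing in the score.
#'
#' @param target_scores Relevance scores of the target curves.
#' @param decoy_scores Relevance scores of the decoy curves.
#' @return Data frame aligned with `target_scores`: columns `score`,
#'   `raw_fdr`, `q`.
#' @export
compute_qvalues <- function(target_scores, decoy_scores) {
  if (!length(target_scores) || !length(decoy_scores)) {
    stop("need non-empty target and decoy score sets")
  }
  nt <- length(target_scores)
  nd <- length(decoy_scores)
  st_sorted <- sort(target_scores)
  sd_sorted <- sort(decoy_scores)
  # inclusive counts at threshold s: #{x >= s} = N - #{x < s}
  n_t_ge <- nt - findInterval(target_scores, st_sorted, left.open = TRUE)
  n_d_ge <- nd - findInterval(target_scores, sd_sorted, left.open = TRUE)
  raw <- n_d_ge * (nt / nd) / n_t_ge
  # q_i = min raw FDR over thresholds at or below the curve's score
  ord <- order(target_scores)
  q <- numeric(nt)
  q[ord] <- cummin(raw[ord])
  data.frame(score = target_scores, raw_fdr = pmin(raw, 1), q = pmin(q, 1))
}

#' FDR at a fixed decision threshold
#'
#' Rescaled decoy-to-target ratio among curves at or above the threshold:
#' `#\{decoys >= t\} * (N_targets/N_decoys) / #\{targets >= t\}`. `NA` when no
#' target reaches the threshold.
#'
#' @param target_scores,decoy_scores Relevance scores.
#' @param threshold Decision threshold on the relevance score (e.g.
#'   `-log10(alpha)`).
#' @return Estimated FDR in \[0, 1\], or `NA` if undefined.
#' @export
fdr_at_boundary <- function(target_scores, decoy_scores, threshold) {
  nt_ge <- sum(target_scores >= threshold)
  if (nt_ge == 0) return(NA_real_)
  nd_ge <- sum(decoy_scores >= threshold)
  min(nd_ge * (length(target_scores) / length(decoy_scores)) / nt_ge, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjusted p-values (via [stats::p.adjust()]); the
#' effect-size-agnostic comparison to the target-decoy relevance-score
#' procedure.
#'
#' @param p_values p-values in \[0, 1\].
#' @return Monotone adjusted q-values.
#' @export
bh_qvalues <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}
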