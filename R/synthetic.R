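#' Log-spaced dose grid
#'
#' Default experimental design for simulated curves: `n` log10-equispaced
#' doses ending at `top` and spanning `decades` orders of magnitude. The
#' default (10 doses from 1 nM to 10 uM) mirrors a typical deep-coverage
#' dose-response screen.
#'
#' @param n Number of doses (>= 5 for a 4-parameter fit with spare df).
#' @param decades Orders of magnitude spanned.
#' @param top Log10 of the highest dose in molar.
#' @return Numeric vector of log10 doses, increasing.
#' @export
dose_grid <- function(n = 10, decades = 5, top = -4) {
  stopifnot(n >= 2, decades > 0)
  seq(top - decades, top, length.out = n)
}

#' Stand-in curve-level noise distribution
#'
#' Draws per-curve standard deviations from a truncated log-normal:
#' `log10(sigma) ~ N(-1.3, 0.35)` truncated to `sigma` in
#' \[0.005, 0.5\]. This is a synthetic stand-in with the qualitative shape of
#' empirical ratio-data variance distributions (median sigma ~0.05, long
#' right tail); it is not derived from any published dataset.
#'
#' @param m Number of draws.
#' @param meanlog10,sdlog10 Location and spread of `log10(sigma)`.
#' @param range Truncation interval for `sigma` (resampling rejection).
#' @return `m` standard deviations.
#' @export
sigma_standin <- function(m, meanlog10 = -1.3, sdlog10 = 0.35,
                          range = c(0.005, 0.5)) {
  out <- numeric(0)
  while (length(out) < m) {
    s <- 10^rnorm(m, meanlog10, sdlog10)
    out <- c(out, s[s >= range[1] & s <= range[2]])
  }
  out[seq_len(m)]
}

#' Simulated datasets with known ground truth
#'
#' Generators for testing every pipeline stage without external data.
#' `make_null_dataset()` produces flat-truth curves (response independent of
#' dose); `make_regulated_dataset()` produces genuinely dose-dependent
#' curves from the log-logistic model with known parameters;
#' `make_mixture_dataset()` shuffles the two together. All return the curve
#' list plus a `truth` data frame so recovery, power and FDR can be
#' evaluated against the generating truth.
#'
#' Regulated truth distributions: pEC50 uniform over the dose range shrunk
#' by `pec50_margin` decades on each side (so effect sizes are not
#' edge-compressed by design), slope uniform on `slope_range`, and signed
#' log2 fold change with magnitude uniform on `cfc_range` (front plateau 1,
#' back plateau `2^cfc`). Noise: per-curve sigma from `variance_source`
#' (default [sigma_standin()]), or a fixed number.
#'
#' @param n_curves Number of curves.
#' @param doses Log10 dose grid.
#' @param variance_source Function `f(m)` returning standard deviations, a
#'   numeric vector of variances to resample, or a single fixed sigma.
#' @param seed Integer seed (required for reproducibility).
#' @return List with `curves` (list of [curve_data()]), `truth`
#'   (data frame with `curve_id`, `label`, `sigma` and, for regulated
#'   curves, `pEC50`, `slope`, `front`, `back`, `cfc`).
#' @export
make_null_dataset <- function(n_curves, doses = dose_grid(),
                              variance_source = sigma_standin, seed) {
  if (!missing(seed)) set.seed(seed)
  curves <- simulate_null_curves(n_curves, doses,
                                 variance_source = as_sigma_fun(variance_source))
  sigma <- attr(curves, "sigma")
  truth <- data.frame(curve_id = vapply(curves, `[[`, "", "curve_id"),
                      label = "null", sigma = sigma,
                      pEC50 = NA_real_, slope = NA_real_,
                      front = 1, back = 1, cfc = 0)
  list(curves = curves, truth = truth)
}

#' @rdname make_null_dataset
#' @param cfc_range Range of |log2 fold change| magnitudes for regulated
#'   truth (default \[0.5, 2\]).
#' @param sign One of `"both"`, `"down"`, `"up"`: direction(s) of
#'   regulation.
#' @param slope_range Range of truth slopes.
#' @param pec50_margin Decades the truth EC50 stays inside the dose range.
#' @export
make_regulated_dataset <- function(n_curves, doses = dose_grid(),
                                   variance_source = sigma_standin,
                                   cfc_range = c(0.5, 2),
                                   sign = c("both", "down", "up"),
                                   slope_range = c(0.5, 2),
                                   pec50_margin = 1, seed) {
  sign <- match.arg(sign)
  if (!missing(seed)) set.seed(seed)
  xr <- range(doses)
  if (diff(xr) <= 2 * pec50_margin) {
    stop("dose range too narrow for the requested pEC50 margin")
  }
  pec50 <- runif(n_curves, -(xr[2] - pec50_margin), -(xr[1] + pec50_margin))
  slope <- runif(n_curves, slope_range[1], slope_range[2])
  mag <- runif(n_curves, cfc_range[1], cfc_range[2])
  sgn <- switch(sign,
                both = sample(c(-1, 1), n_curves, replace = TRUE),
                down = rep(-1, n_curves),
                up = rep(1, n_curves))
  cfc <- sgn * mag
  sigma <- draw_sigma(as_sigma_fun(variance_source), n_curves)
  ids <- sprintf("reg_%06d", seq_len(n_curves))
  curves <- vector("list", n_curves)
  for (i in seq_len(n_curves)) {
    pars <- c(pEC50 = pec50[i], slope = slope[i], front = 1, back = 2^cfc[i])
    y <- loglogistic_eval(pars, doses) + rnorm(length(doses), sd = sigma[i])
    curves[[i]] <- curve_data(doses, y, curve_id = ids[i])
  }
  truth <- data.frame(curve_id = ids, label = ifelse(cfc > 0, "up", "down"),
                      sigma = sigma, pEC50 = pec50, slope = slope,
                      front = 1, back = 2^cfc, cfc = cfc)
  list(curves = curves, truth = truth)
}

#' @rdname make_null_dataset
#' @param fraction_regulated Fraction of curves drawn from the regulated
#'   generator (in \[0, 1\]).
#' @param ... Passed on to [make_regulated_dataset()].
#' @export
make_mixture_dataset <- function(n_curves, fraction_regulated,
                                 doses = dose_grid(),
                                 variance_source = sigma_standin,
                                 seed, ...) {
  stopifnot(fraction_regulated >= 0, fraction_regulated <= 1)
  if (!missing(seed)) set.seed(seed)
  n_reg <- round(n_curves * fraction_regulated)
  n_null <- n_curves - n_reg
  parts <- list()
  if (n_reg > 0) {
    parts$reg <- make_regulated_dataset(n_reg, doses, variance_source, ...)
  }
  if (n_null > 0) {
    parts$null <- make_null_dataset(n_null, doses, variance_source)
  }
  curves <- c(if (n_reg > 0) parts$reg$curves, if (n_null > 0) parts$null$curves)
  truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
  perm <- sample(length(curves))
  truth <- truth[perm, , drop = FALSE]
  rownames(truth) <- NULL
  list(curves = curves[perm], truth = truth)
}

# accept a function, a variance vector, or a single fixed sigma
as_sigma_fun <- function(variance_source) {
  if (is.numeric(variance_source) && length(variance_source) == 1) {
    s <- variance_source
    return(function(m) rep(s, m))
  }
  variance_source
}

#' Write a simulated dataset in the canonical input dialect
#'
#' Writes the response table (TSV: id column plus one column per dose) and
#' the truth table next to it, so simulated data can be round-tripped
#' through the file-based pipeline.
#'
#' @param dataset A list as returned by the `make_*_dataset()` generators.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(dataset, dir, prefix = "simulated") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  curves <- dataset$curves
  doses_log10 <- curves[[1]]$x
  mat <- t(vapply(curves, function(cv) cv$y, numeric(length(doses_log10))))
  colnames(mat) <- sprintf("dose_%02d", seq_along(doses_log10))
  tab <- data.frame(curve_id = vapply(curves, `[[`, "", "curve_id"), mat,
                    check.names = FALSE)
  data_path <- file.path(dir, paste0(prefix, "_data.tsv"))
  truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write.table(tab, data_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dataset$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(data = data_path, truth = truth_path,
              doses = paste(10^doses_log10, collapse = ",")))
}
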