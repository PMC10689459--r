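#' Run the full dose-response significance pipeline
#'
#' Orchestrates read/preprocess, multi-start fitting, recalibrated
#' F-statistics and p-values, fold changes, s0-adjusted relevance scores,
#' classification, and (optionally) decoy-based FDR estimation. Input can
#' be a file in the canonical dialect, a list of [curve_data()] objects, or
#' a simulated dataset from the `make_*_dataset()` generators. All
#' randomness (decoys, null simulation) is controlled by the config seed
#' through fixed per-stage derivations, so a run is reproducible and
#' worker-count independent.
#'
#' @param config A [drc_config()] (or path to a TOML file).
#' @param input Input table path, list of [curve_data()], or a dataset list
#'   with a `curves` element. Ignored when `random` is given.
#' @param fdr Override `config$fdr$enabled`.
#' @param random If a positive integer, analyse that many simulated null
#'   curves instead of `input` (p-value calibration mode).
#' @param threads Number of worker processes for fitting (results are
#'   identical for any value).
#' @return An object of class `drc_screen`: list with `results` (one row
#'   per curve), `boundary`, `config`, `manifest`, and -- when FDR is on --
#'   `decoy_scores` and `fdr_at_boundary`.
#'
#' @examples
#' cfg <- drc_config(doses = 10^seq(-9, -4, length.out = 10), fc_lim = 0.3)
#' ds <- make_mixture_dataset(60, 0.2, doses = log10(cfg$experiment$doses),
#'                            seed = 7)
#' scr <- run_pipeline(cfg, ds)
#' table(scr$results$label)
#' @export
run_pipeline <- function(config, input = NULL, fdr = NULL, random = NULL,
                         threads = 1) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "drc_config"))
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(config_hash = config_hash(config),
                   seed = config$io$seed, warnings = character(0),
                   stages = list())
  seed <- as.integer(config$io$seed)

  # -- acquire curves ------------------------------------------------------
  excluded <- data.frame(curve_id = character(0), reason = character(0))
  run_log <- character(0)
  if (!is.null(random)) {
    stopifnot(random >= 1)
    curves <- simulate_null_curves(random, doses = log10(config$experiment$doses),
                                   seed = stage_seed(seed, "random"))
    run_log <- c(run_log, sprintf("simulated %d null curves", length(curves)))
  } else if (is.character(input)) {
    rd <- read_curve_table(input, config)
    curves <- rd$curves
    excluded <- rd$excluded
    run_log <- c(run_log, rd$log)
  } else if (is.list(input) && !is.null(input$curves)) {
    curves <- input$curves
  } else if (is.list(input) && length(input) && inherits(input[[1]], "curve_data")) {
    curves <- input
  } else {
    stop("no usable input: give a file path, curve list, dataset, or random = N")
  }
  if (!length(curves)) stop("no curves to analyse after exclusions")
  manifest$stages$input <- list(n_curves = length(curves),
                                n_excluded = nrow(excluded))

  calib <- config_calib(config)
  boundary <- config_boundary(config)

  # -- fit + statistics ----------------------------------------------------
  t1 <- proc.time()[["elapsed"]]
  results <- screen_curves(curves, config, threads = threads)
  manifest$stages$fit <- list(n_fitted = nrow(results),
                              n_converged = sum(results$converged),
                              seconds = proc.time()[["elapsed"]] - t1)

  # -- relevance + classification -----------------------------------------
  results$s0 <- s0_by_n(boundary, results$n)
  results$f_adj <- adjusted_f(results$f_value, results$cfc, results$s0)
  results$relevance <- relevance_score(results$f_adj, results$n, calib)
  results$label <- classify_curves(results$relevance, results$cfc,
                                   results$intercept, results$rmse_m0,
                                   p = results$p_value, boundary = boundary)

  # -- decoy FDR -----------------------------------------------------------
  do_fdr <- if (is.null(fdr)) isTRUE(config$fdr$enabled) else isTRUE(fdr)
  out <- list(results = results, boundary = boundary, config = config,
              excluded = excluded, log = run_log)
  if (do_fdr) {
    t2 <- proc.time()[["elapsed"]]
    variances <- estimate_variances(split_bundles(results))
    n_dec <- config$fdr$n_decoys
    if (!is.finite(n_dec) || n_dec < 1) n_dec <- nrow(results)
    doses_fit <- curves[[which.max(vapply(curves, `[[`, 0, "n"))]]$x
    decoys <- generate_decoys(variances, doses_fit, n_decoys = n_dec,
                              seed = stage_seed(seed, "decoys"))
    dres <- screen_curves(decoys, config, threads = threads)
    dres$s0 <- s0_by_n(boundary, dres$n)
    dres$f_adj <- adjusted_f(dres$f_value, dres$cfc, dres$s0)
    dres$relevance <- relevance_score(dres$f_adj, dres$n, calib)
    qv <- compute_qvalues(results$relevance, dres$relevance)
    results$q_value <- qv$q
    out$results <- results
    out$decoy_scores <- dres$relevance
    out$fdr_at_boundary <- fdr_at_boundary(results$relevance, dres$relevance,
                                           -log10(boundary$alpha))
    manifest$stages$fdr <- list(n_decoys = n_dec,
                                n_excluded_variances = attr(variances, "n_excluded"),
                                fdr_at_boundary = out$fdr_at_boundary,
                                seconds = proc.time()[["elapsed"]] - t2)
  }
  manifest$labels <- table(results$label)
  manifest$seconds_total <- proc.time()[["elapsed"]] - t0
  out$manifest <- manifest
  class(out) <- "drc_screen"
  out
}

# deterministic fan-out of the global seed into stage-specific seeds
stage_seed <- function(seed, stage) {
  offset <- switch(stage, random = 101L, decoys = 211L, fixtures = 307L,
                   stop("unknown stage: ", stage))
  (as.integer(seed) * 1009L + offset) %% 2147483647L
}

config_calib <- function(config) {
  s <- config$statistic
  f_calibration(dfn = s$dfn, loc = s$loc, scale = s$scale, k = s$k)
}

config_boundary <- function(config) {
  cl <- config$classification
  drc_boundary(alpha = cl$alpha, fc_lim = cl$fc_lim,
               rmse_limit = cl$rmse_limit, not_p_min = cl$not_p_min,
               intercept_space = cl$intercept_space,
               calib = config_calib(config), s0_use_loc = cl$s0_use_loc)
}

# s0 per curve, computed once per distinct n
s0_by_n <- function(boundary, n) {
  un <- sort(unique(n))
  s0u <- compute_s0(boundary$alpha, boundary$fc_lim, un, boundary$calib,
                    boundary$s0_use_loc)
  s0u[match(n, un)]
}

# fit every curve and assemble the per-curve results table
screen_curves <- function(curves, config, threads = 1) {
  calib <- config_calib(config)
  control <- fit_control(tol = config$fit$tol, maxit = config$fit$maxit,
                         min_n = config$fit$min_n)
  fc_mode <- config$classification$fc_mode
  objective <- config$fit$objective
  one <- function(cv) {
    fit <- fit_loglogistic(cv, objective = objective, control = control)
    st <- curve_statistics(fit, cv, calib = calib, fc_mode = fc_mode)
    c(n = fit$n, pEC50 = unname(fit$params[["pEC50"]]),
      slope = unname(fit$params[["slope"]]),
      front = unname(fit$params[["front"]]),
      back = unname(fit$params[["back"]]),
      intercept = fit$mean_fit$intercept,
      sse_m0 = fit$sse_m0, sse_m1 = fit$sse_m1, rmse_m0 = fit$rmse_m0,
      f_value = st$f, dfd = st$dfd, p_value = st$p, cfc = st$cfc,
      converged = as.numeric(fit$converged))
  }
  rows <- if (threads > 1) {
    parallel::mclapply(curves, one, mc.cores = threads)
  } else {
    lapply(curves, one)
  }
  df <- as.data.frame(do.call(rbind, rows))
  df$converged <- df$converged > 0
  data.frame(curve_id = vapply(curves, `[[`, "", "curve_id"), df,
             stringsAsFactors = FALSE)
}

# reconstruct minimal fit bundles (sse_m1, n) for variance estimation
split_bundles <- function(results) {
  lapply(seq_len(nrow(results)), function(i) {
    list(sse_m1 = results$sse_m1[i], n = results$n[i])
  })
}

#' @export
print.drc_screen <- function(x, ...) {
  cat("Dose-response screen:", nrow(x$results), "curves\n")
  print(x$manifest$labels)
  cat(sprintf("boundary: alpha = %g, fc_lim = %g\n",
              x$boundary$alpha, x$boundary$fc_lim))
  if (!is.null(x$fdr_at_boundary)) {
    cat(sprintf("decoy-estimated FDR at the boundary: %.4g\n",
                x$fdr_at_boundary))
  }
  invisible(x)
}

#' @export
summary.drc_screen <- function(object, ...) {
  res <- object$results
  out <- list(n = nrow(res), labels = table(res$label),
              n_excluded = nrow(object$excluded),
              boundary = object$boundary,
              median_rmse = median(res$rmse_m0),
              fdr_at_boundary = object$fdr_at_boundary)
  class(out) <- "summary.drc_screen"
  out
}

#' @export
print.summary.drc_screen <- function(x, ...) {
  cat("Curves analysed:", x$n, " (excluded:", x$n_excluded, ")\n")
  print(x$labels)
  cat(sprintf("alpha = %g, fc_lim = %g, median mean-model RMSE = %.4g\n",
              x$boundary$alpha, x$boundary$fc_lim, x$median_rmse))
  if (!is.null(x$fdr_at_boundary) && is.finite(x$fdr_at_boundary)) {
    cat(sprintf("decoy-estimated FDR at the boundary: %.4g\n",
                x$fdr_at_boundary))
  }
  invisible(x)
}

#' Per-dose-column quality control summary
#'
#' Residuals of every fitted curve are grouped by dose position; for each
#' position the median absolute residual and the median signed residual
#' (bias) are reported. Positions whose median absolute residual exceeds
#' twice the across-position median are flagged as likely problematic
#' experiments. Flagging is suppressed when fewer than two curves are
#' available.
#'
#' @param curves List of [curve_data()] used in the screen.
#' @param results Results table from [run_pipeline()] (parameter columns
#'   are used to reconstruct the fitted values).
#' @return Data frame: `x` (log10 dose), `n_curves`,
#'   `median_abs_residual`, `median_bias`, `flagged`.
#' @export
qc_summary <- function(curves, results) {
  if (!length(curves)) stop("no curves supplied")
  idx <- match(vapply(curves, `[[`, "", "curve_id"), results$curve_id)
  xs <- ys <- rs <- list()
  for (i in seq_along(curves)) {
    j <- idx[i]
    if (is.na(j)) next
    cv <- curves[[i]]
    pars <- c(pEC50 = results$pEC50[j], slope = results$slope[j],
              front = results$front[j], back = results$back[j])
    xs[[i]] <- cv$x
    rs[[i]] <- cv$y - loglogistic_eval(pars, cv$x)
  }
  x_all <- unlist(xs)
  r_all <- unlist(rs)
  key <- round(x_all, 10)
  grp <- split(r_all, key)
  out <- data.frame(x = as.numeric(names(grp)),
                    n_curves = vapply(grp, length, integer(1)),
                    median_abs_residual = vapply(grp, function(r) median(abs(r)), numeric(1)),
                    median_bias = vapply(grp, median, numeric(1)))
  rownames(out) <- NULL
  ref <- median(out$median_abs_residual)
  out$flagged <- if (length(curves) < 2) rep(FALSE, nrow(out)) else {
    out$median_abs_residual > 2 * ref
  }
  out
}
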