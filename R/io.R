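#' Parse a TOML parameter file (subset)
#'
#' Minimal TOML reader covering what pipeline configuration needs:
#' `[section]` tables, `key = value` pairs with strings, numbers, booleans
#' and (possibly multi-line) arrays, and `#` comments. Nested tables,
#' dates and inline tables are not supported.
#'
#' @param path Path to a TOML file, or a character vector of lines via
#'   `text`.
#' @param text Optional character vector of TOML lines (overrides `path`).
#' @return Nested named list: `out$section$key`.
#' @export
parse_toml <- function(path, text = NULL) {
  lines <- if (is.null(text)) readLines(path, warn = FALSE) else text
  out <- list()
  section <- NULL
  i <- 1
  while (i <= length(lines)) {
    line <- strip_toml_comment(lines[i])
    i <- i + 1
    if (!nzchar(trimws(line))) next
    line <- trimws(line)
    if (grepl("^\\[.+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop("malformed TOML line: ", line)
    key <- trimws(substr(line, 1, eq - 1))
    val <- trimws(substr(line, eq + 1, nchar(line)))
    # multi-line array: accumulate until brackets balance
    while (startsWith(val, "[") && !toml_balanced(val)) {
      if (i > length(lines)) stop("unterminated array for key '", key, "'")
      val <- paste(val, trimws(strip_toml_comment(lines[i])))
      i <- i + 1
    }
    parsed <- parse_toml_value(val)
    if (is.null(section)) out[[key]] <- parsed else out[[section]][[key]] <- parsed
  }
  out
}

strip_toml_comment <- function(line) {
  chars <- strsplit(line, "")[[1]]
  in_str <- FALSE
  for (j in seq_along(chars)) {
    if (chars[j] == '"') in_str <- !in_str
    if (chars[j] == "#" && !in_str) return(substr(line, 1, j - 1))
  }
  line
}

toml_balanced <- function(s) {
  chars <- strsplit(s, "")[[1]]
  sum(chars == "[") == sum(chars == "]")
}

parse_toml_value <- function(val) {
  if (startsWith(val, "[")) {
    inner <- trimws(gsub("^\\[|\\]$", "", val))
    if (!nzchar(inner)) return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    parts <- parts[nzchar(parts)]
    vals <- lapply(parts, parse_toml_value)
    return(unlist(vals))
  }
  if (grepl('^".*"$', val)) return(gsub('^"|"$', "", val))
  if (val %in% c("true", "false")) return(val == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  stop("cannot parse TOML value: ", val)
}

#' Serialise a configuration to TOML
#'
#' Writes the sections and keys of a [drc_config()] so that
#' `parse -> serialise -> parse` round-trips to identical settings.
#'
#' @param config A [drc_config()] or plain nested list.
#' @param path Output path; if `NULL`, the TOML text is returned.
#' @return Invisibly the path, or the text if `path` is `NULL`.
#' @export
write_toml <- function(config, path = NULL) {
  fmt_val <- function(v) {
    if (is.character(v)) paste0('"', v, '"')
    else if (is.logical(v)) ifelse(v, "true", "false")
    else sprintf("%.17g", v)
  }
  lines <- character(0)
  for (section in names(config)) {
    v <- config[[section]]
    if (!is.list(v)) next
    lines <- c(lines, paste0("[", section, "]"))
    for (key in names(v)) {
      item <- v[[key]]
      if (is.null(item) || !length(item)) next
      vals <- vapply(unlist(item), fmt_val, "")
      rhs <- if (length(vals) > 1 || is.list(item)) {
        paste0("[", paste(vals, collapse = ", "), "]")
      } else vals
      lines <- c(lines, paste0(key, " = ", rhs))
    }
    lines <- c(lines, "")
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with validated defaults. Doses
#' are given in molar and converted to log10 internally; response columns
#' are matched to doses by position. Control columns are flagged explicitly
#' (a zero-dose control cannot be inferred from a log-dose axis) and are
#' anchored `control_offset` decades below the lowest dose.
#'
#' @param doses Numeric molar concentrations, one per response column.
#' @param response_columns Column names holding the responses, aligned with
#'   `doses` (default `dose_01`, `dose_02`, ...).
#' @param control_columns Column names of control (zero-dose) samples;
#'   may be empty.
#' @param control_offset Decades below the lowest dose at which the control
#'   pseudo log-dose is placed (default 2).
#' @param id_column Name of the curve identifier column.
#' @param delimiter Input field delimiter (default tab).
#' @param objective `"OLS"` or `"MLE"`.
#' @param weights Optional per-response-column weights.
#' @param min_n,tol,maxit Fitting controls, see [fit_control()].
#' @param dfn,loc,scale,k Calibration constants, see [f_calibration()].
#' @param alpha,fc_lim,rmse_limit,not_p_min,intercept_space,s0_use_loc
#'   Classification boundary, see [drc_boundary()].
#' @param fc_mode Fold-change mode, see [fold_change()].
#' @param median_center Median-center response columns before analysis.
#' @param impute Impute missing values with the low-intensity quantile.
#' @param impute_quantile Imputation quantile in (0, 0.5), default 0.005.
#' @param max_missing Maximum missing values tolerated per curve before
#'   exclusion (default 4).
#' @param fdr Enable decoy-based FDR estimation.
#' @param n_decoys Number of decoy curves (0 = match the target count).
#' @param seed Global seed; stage seeds are derived deterministically.
#' @param output Results path used by [write_results()].
#' @return A nested list of class `drc_config` with sections `experiment`,
#'   `fit`, `statistic`, `classification`, `preprocessing`, `fdr`, `io`.
#' @export
drc_config <- function(doses,
                       response_columns = sprintf("dose_%02d", seq_along(doses)),
                       control_columns = character(0),
                       control_offset = 2,
                       id_column = "curve_id",
                       delimiter = "\t",
                       objective = "OLS",
                       weights = NULL,
                       min_n = 5, tol = 1e-10, maxit = 500,
                       dfn = 5, loc = 0.12, scale = 1, k = 4,
                       alpha = 0.05, fc_lim = 0.45, rmse_limit = 0.1,
                       not_p_min = NULL,
                       intercept_space = "log2", s0_use_loc = FALSE,
                       fc_mode = "range",
                       median_center = FALSE, impute = FALSE,
                       impute_quantile = 0.005, max_missing = 4,
                       fdr = FALSE, n_decoys = 0,
                       seed = 1, output = "results.tsv") {
  doses <- as.numeric(doses)
  if (length(doses) != length(response_columns)) {
    stop("doses and response_columns must align (",
         length(doses), " vs ", length(response_columns), ")")
  }
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    stop("doses must be positive molar concentrations; flag controls via control_columns")
  }
  if (impute_quantile <= 0 || impute_quantile >= 0.5) {
    stop("impute_quantile must lie in (0, 0.5)")
  }
  if (!is.null(weights) && length(weights) != length(doses)) {
    stop("weights must align with response columns")
  }
  cfg <- list(
    experiment = list(doses = doses,
                      response_columns = as.character(response_columns),
                      control_columns = as.character(control_columns),
                      control_offset = control_offset),
    fit = list(objective = objective, min_n = min_n, tol = tol,
               maxit = maxit, weights = weights),
    statistic = list(dfn = dfn, loc = loc, scale = scale, k = k),
    classification = list(alpha = alpha, fc_lim = fc_lim,
                          rmse_limit = rmse_limit, not_p_min = not_p_min,
                          intercept_space = intercept_space,
                          s0_use_loc = s0_use_loc, fc_mode = fc_mode),
    preprocessing = list(median_center = median_center, impute = impute,
                         impute_quantile = impute_quantile,
                         max_missing = max_missing),
    fdr = list(enabled = fdr, n_decoys = n_decoys),
    io = list(id_column = id_column, delimiter = delimiter, output = output,
              seed = seed)
  )
  class(cfg) <- "drc_config"
  cfg
}

#' Read a pipeline configuration from a TOML file
#'
#' @param path TOML file with sections `[experiment]`, `[fit]`,
#'   `[statistic]`, `[classification]`, `[preprocessing]`, `[fdr]`, `[io]`;
#'   all keys optional except `experiment.doses`.
#' @return A validated [drc_config()].
#' @export
read_config <- function(path) {
  raw <- parse_toml(path)
  get <- function(section, key) raw[[section]][[key]]
  args <- list()
  put <- function(name, val) if (!is.null(val)) args[[name]] <<- val
  put("doses", get("experiment", "doses"))
  put("response_columns", get("experiment", "response_columns"))
  put("control_columns", get("experiment", "control_columns"))
  put("control_offset", get("experiment", "control_offset"))
  put("objective", get("fit", "objective"))
  put("weights", get("fit", "weights"))
  put("min_n", get("fit", "min_n"))
  put("tol", get("fit", "tol"))
  put("maxit", get("fit", "maxit"))
  put("dfn", get("statistic", "dfn"))
  put("loc", get("statistic", "loc"))
  put("scale", get("statistic", "scale"))
  put("k", get("statistic", "k"))
  put("alpha", get("classification", "alpha"))
  put("fc_lim", get("classification", "fc_lim"))
  put("rmse_limit", get("classification", "rmse_limit"))
  put("not_p_min", get("classification", "not_p_min"))
  put("intercept_space", get("classification", "intercept_space"))
  put("s0_use_loc", get("classification", "s0_use_loc"))
  put("fc_mode", get("classification", "fc_mode"))
  put("median_center", get("preprocessing", "median_center"))
  put("impute", get("preprocessing", "impute"))
  put("impute_quantile", get("preprocessing", "impute_quantile"))
  put("max_missing", get("preprocessing", "max_missing"))
  put("fdr", get("fdr", "enabled"))
  put("n_decoys", get("fdr", "n_decoys"))
  put("id_column", get("io", "id_column"))
  put("delimiter", get("io", "delimiter"))
  put("output", get("io", "output"))
  put("seed", get("io", "seed"))
  if (is.null(args$doses)) stop("config must provide experiment.doses")
  do.call(drc_config, args)
}

#' Write a configuration to a TOML file
#'
#' @param config A [drc_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "drc_config"))
  cfg <- unclass(config)
  # rename keys that differ between the constructor and the TOML dialect
  cfg$fdr <- list(enabled = cfg$fdr$enabled, n_decoys = cfg$fdr$n_decoys)
  write_toml(cfg, path)
}

#' Median-center response columns
#'
#' Multiplicative centering in intensity space: each column is divided by
#' its median and rescaled to the grand median of all finite values, so all
#' columns end up with equal medians while the overall intensity scale is
#' preserved. Missing values are ignored in the medians.
#'
#' @param mat Numeric matrix (curves x response columns).
#' @return Centered matrix of the same shape.
#' @export
median_center <- function(mat) {
  mat <- as.matrix(mat)
  col_med <- apply(mat, 2, median, na.rm = TRUE)
  if (any(!is.finite(col_med))) {
    stop("column(s) without finite values: ",
         paste(which(!is.finite(col_med)), collapse = ", "))
  }
  grand <- median(mat[is.finite(mat)])
  sweep(mat, 2, col_med, "/") * grand
}

#' Impute missing values with a low quantile
#'
#' Replaces missing cells with the per-table intensity quantile of the
#' observed values (default the 0.5% quantile), emulating
#' detection-limit imputation for intensity data.
#'
#' @param mat Numeric matrix.
#' @param quantile Imputation quantile, in (0, 0.5).
#' @return Matrix with missing cells filled; attribute `"n_imputed"`.
#' @export
impute_missing <- function(mat, quantile = 0.005) {
  if (quantile <= 0 || quantile >= 0.5) {
    stop("imputation quantile must lie in (0, 0.5)")
  }
  mat <- as.matrix(mat)
  obs <- mat[is.finite(mat)]
  if (!length(obs)) stop("no observed values to impute from")
  fill <- stats::quantile(obs, quantile, names = FALSE, type = 7)
  missing <- !is.finite(mat)
  mat[missing] <- fill
  attr(mat, "n_imputed") <- sum(missing)
  mat
}

#' Normalize responses to the control sample
#'
#' Divides each row by the mean of its control columns so responses become
#' ratios with the control at 1. Rows whose control mean is missing or
#' non-positive cannot be normalized and are flagged for exclusion.
#'
#' @param mat Numeric matrix including the control column(s).
#' @param control_columns Column names (or indices) of the controls.
#' @return List: `ratios` (matrix, all columns divided by the row control
#'   mean), `control_mean` (vector), `excluded` (row indices that failed).
#' @export
normalize_to_control <- function(mat, control_columns) {
  mat <- as.matrix(mat)
  if (!length(control_columns)) stop("no control columns given")
  ctrl <- mat[, control_columns, drop = FALSE]
  cm <- rowMeans(ctrl, na.rm = TRUE)
  bad <- !is.finite(cm) | cm <= 0
  ratios <- mat / cm
  list(ratios = ratios, control_mean = cm, excluded = which(bad))
}

#' Read a dose-response table into curves
#'
#' Reads the canonical input dialect (delimited text, one row per curve, an
#' id column plus response columns named in the configuration), applies the
#' configured preprocessing in the order median-center, impute, normalize
#' to control, and returns one [curve_data()] per usable row. Rows are
#' excluded -- with the reason recorded -- when they have more than
#' `max_missing` missing responses, a non-positive control, or fewer usable
#' points than the fitting minimum.
#'
#' @param path Input file.
#' @param config A [drc_config()] naming the id, response and control
#'   columns and the doses.
#' @return List: `curves` (list of [curve_data()]), `excluded` (data frame
#'   `curve_id`, `reason`), `log` (character lines of the exclusion
#'   ledger).
#' @export
read_curve_table <- function(path, config) {
  stopifnot(inherits(config, "drc_config"))
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- read.delim(path, sep = config$io$delimiter, check.names = FALSE,
                    na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("input table is empty: ", path)
  exp <- config$experiment
  idc <- config$io$id_column
  if (!idc %in% names(tab)) stop("id column '", idc, "' not found in ", path)
  ids <- as.character(tab[[idc]])
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop("duplicate curve ids at data rows: ", paste(dup, collapse = ", "))
  }
  need <- c(exp$response_columns, exp$control_columns)
  miss_cols <- setdiff(need, names(tab))
  if (length(miss_cols)) {
    stop("response/control columns missing from input: ",
         paste(miss_cols, collapse = ", "))
  }
  raw <- as.matrix(tab[, need, drop = FALSE])
  storage.mode(raw) <- "double"

  log <- character(0)
  excl <- data.frame(curve_id = character(0), reason = character(0))
  drop_rows <- function(idx, reason) {
    if (length(idx)) {
      excl <<- rbind(excl, data.frame(curve_id = ids[idx], reason = reason))
      log <<- c(log, sprintf("excluded %d curve(s): %s", length(idx), reason))
    }
  }

  n_miss <- rowSums(!is.finite(raw))
  bad_missing <- which(n_miss > config$preprocessing$max_missing)
  drop_rows(bad_missing, sprintf("more than %d missing values",
                                 config$preprocessing$max_missing))

  if (isTRUE(config$preprocessing$median_center)) {
    raw <- median_center(raw)
    log <- c(log, "median-centered response columns")
  }
  if (isTRUE(config$preprocessing$impute)) {
    raw <- impute_missing(raw, config$preprocessing$impute_quantile)
    log <- c(log, sprintf("imputed %d missing cells at the %.3g quantile",
                          attr(raw, "n_imputed"),
                          config$preprocessing$impute_quantile))
  }

  has_controls <- length(exp$control_columns) > 0
  if (has_controls) {
    nm <- normalize_to_control(raw, exp$control_columns)
    bad_ctrl <- setdiff(nm$excluded, bad_missing)
    drop_rows(bad_ctrl, "non-positive or missing control")
    ratios <- nm$ratios
  } else {
    ratios <- raw
  }

  x_doses <- log10(exp$doses)
  x_ctrl <- if (has_controls) {
    rep(control_pseudo_dose(x_doses, exp$control_offset),
        length(exp$control_columns))
  } else numeric(0)
  w_resp <- if (is.null(config$fit$weights)) rep(1, length(x_doses))
            else config$fit$weights
  x_all <- c(x_ctrl, x_doses)
  w_all <- c(rep(1, length(x_ctrl)), w_resp)
  y_cols <- c(exp$control_columns, exp$response_columns)

  keep <- setdiff(seq_len(nrow(ratios)), unique(excl_idx(excl, ids)))
  curves <- vector("list", 0)
  short <- integer(0)
  for (i in keep) {
    cv <- curve_data(x_all, ratios[i, y_cols], w_all, curve_id = ids[i])
    if (cv$n < config$fit$min_n) short <- c(short, i) else curves <- c(curves, list(cv))
  }
  drop_rows(short, sprintf("fewer than %d usable points", config$fit$min_n))
  log <- c(log, sprintf("read %d rows: %d curves retained, %d excluded",
                        nrow(tab), length(curves), nrow(excl)))
  list(curves = curves, excluded = excl, log = log)
}

excl_idx <- function(excl, ids) match(excl$curve_id, ids)

#' Write and re-read the results table
#'
#' The results table is tab-separated with a `#`-prefixed header block
#' recording the package version, configuration hash and seed, followed by
#' one row per curve. Numeric columns are written with full precision so a
#' round trip preserves them.
#'
#' @param results Results data frame (from [run_pipeline()]).
#' @param config The [drc_config()] used.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(results, config, path) {
  hdr <- c(
    sprintf("# doseresp %s", as.character(packageVersion("doseresp"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %d", as.integer(config$io$seed)),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  out[num] <- lapply(out[num], function(v) sprintf("%.12g", v))
  suppressWarnings(write.table(out, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.delim(path, comment.char = "#", check.names = FALSE,
             stringsAsFactors = FALSE)
}

# small polynomial rolling hash over the serialised configuration
config_hash <- function(config) {
  s <- paste(write_toml(unclass(config)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
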