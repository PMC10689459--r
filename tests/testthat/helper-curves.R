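# shared fixtures built in code

std_doses <- dose_grid()  # 10 log10 doses, 1 nM .. 10 uM

# a clean sigmoid plus optional Gaussian noise
toy_curve <- function(pEC50 = 7, slope = 1, front = 1, back = 0.3,
                      sd = 0, doses = std_doses, id = "toy") {
  y <- loglogistic_eval(c(pEC50 = pEC50, slope = slope,
                          front = front, back = back), doses)
  if (sd > 0) y <- y + rnorm(length(doses), sd = sd)
  curve_data(doses, y, curve_id = id)
}

# central finite-difference gradient oracle
fd_gradient <- function(params, x, h_rel = 1e-6) {
  p <- unlist(params)[c("pEC50", "slope", "front", "back")]
  out <- matrix(NA_real_, length(x), 4,
                dimnames = list(NULL, names(p)))
  for (j in seq_along(p)) {
    h <- h_rel * max(abs(p[j]), 1)
    up <- dn <- p
    up[j] <- p[j] + h
    dn[j] <- p[j] - h
    out[, j] <- (loglogistic_eval(up, x) - loglogistic_eval(dn, x)) / (2 * h)
  }
  out
}

# write a small dose-response table in the canonical dialect
write_toy_table <- function(path, mat, ids = sprintf("c%02d", seq_len(nrow(mat))),
                            col_names = sprintf("dose_%02d", seq_len(ncol(mat)))) {
  df <- data.frame(curve_id = ids, mat)
  names(df) <- c("curve_id", col_names)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
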