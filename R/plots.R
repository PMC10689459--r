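#' Volcano and summary plots for a screen
#'
#' `type = "volcano"` draws effect size against `-log10(p)` with the
#' hyperbolic decision boundary; `type = "relevance"` draws the same curves
#' against the relevance score, where the boundary becomes the horizontal
#' line at `-log10(alpha)`; `type = "pec50"` shows the potency histogram of
#' the regulated curves.
#'
#' @param x A `drc_screen` object.
#' @param type Plot type.
#' @param ... Further arguments passed to [plot()].
#' @export
plot.drc_screen <- function(x, type = c("volcano", "relevance", "pec50"), ...) {
  type <- match.arg(type)
  res <- x$results
  b <- x$boundary
  cols <- c(up = "firebrick", down = "royalblue", not = "grey60",
            unclear = "grey85")
  col <- cols[res$label]
  if (type == "volcano") {
    y <- -log10(pmax(res$p_value, 1e-300))
    plot(res$cfc, y, col = col, pch = 16, cex = 0.6,
         xlab = "curve log2 fold change",
         ylab = "-log10 p-value", ...)
    bl <- boundary_line(b, n = stats::median(res$n))
    lines(bl$cfc, bl$neglog10p, lty = 2)
    lines(-bl$cfc, bl$neglog10p, lty = 2)
  } else if (type == "relevance") {
    plot(res$cfc, res$relevance, col = col, pch = 16, cex = 0.6,
         xlab = "curve log2 fold change", ylab = "relevance score", ...)
    abline(h = -log10(b$alpha), lty = 2)
  } else {
    reg <- res[res$label %in% c("up", "down"), ]
    if (nrow(reg)) {
      hist(reg$pEC50, breaks = "FD", xlab = "pEC50",
           main = "regulated curves", ...)
    } else {
      plot(0, 0, type = "n", xlab = "pEC50", ylab = "count",
           main = "regulated curves (none)", ...)
    }
  }
  invisible(x)
}

#' Points along the hyperbolic decision boundary
#'
#' Samples the decision boundary in (fold change, p-value) space: for each
#' |cfc| above the effect-size asymptote, the minimal F-value that is
#' called regulated, mapped to `-log10(p)`. Every sampled point satisfies
#' [hyperbolic_boundary_test()] and lies on the boundary in relevance
#' space.
#'
#' @param boundary A [drc_boundary()].
#' @param n Number of data points the boundary is computed for.
#' @param cfc_max Largest |cfc| sampled.
#' @param length_out Number of samples.
#' @return Data frame `cfc`, `f_min`, `neglog10p`.
#' @export
boundary_line <- function(boundary, n, cfc_max = 4, length_out = 200) {
  calib <- boundary$calib
  q_star <- qf(1 - boundary$alpha, calib$dfn, effective_dfd(n)) * calib$scale +
    calib$loc
  s0 <- compute_s0(boundary$alpha, boundary$fc_lim, n, calib,
                   boundary$s0_use_loc)
  cfc_min <- s0 * sqrt(q_star)
  cfc <- seq(cfc_min * 1.0001 + 1e-9, cfc_max, length.out = length_out)
  f_min <- 1 / (1 / sqrt(q_star) - s0 / cfc)^2
  data.frame(cfc = cfc, f_min = f_min,
             neglog10p = -p_value(f_min, n, calib, log10p = TRUE))
}

#' Write the standard plot set to files
#'
#' Renders the p-value volcano, the relevance-score volcano and the pEC50
#' histogram of regulated curves as PNG files.
#'
#' @param screen A `drc_screen` object.
#' @param dir Output directory (created if missing).
#' @param width,height,res PNG device settings.
#' @return Invisibly, the paths written.
#' @export
plot_outputs <- function(screen, dir, width = 1200, height = 900, res = 150) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("volcano_p.png", "volcano_relevance.png",
                            "pec50_hist.png"))
  types <- c("volcano", "relevance", "pec50")
  for (i in seq_along(paths)) {
    png(paths[i], width = width, height = height, res = res)
    plot(screen, type = types[i])
    dev.off()
  }
  invisible(paths)
}
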