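#' Plot conditional Q-Q strata
#'
#' Base-graphics rendering of [conditional_qq_data()] output: nominal
#' `-log10(p)` on the y-axis against empirical `-log10(q)` on the x-axis,
#' one curve per conditional threshold, with the null diagonal. Leftward
#' shift of tighter strata indicates cross-trait enrichment.
#'
#' @param qq List of `qq_stratum` objects.
#' @param main Plot title.
#' @return `NULL`, invisibly.
#' @export
plot_conditional_qq <- function(qq, main = "Conditional Q-Q") {
  nonempty <- Filter(function(s) s$n_snps > 0, qq)
  if (!length(nonempty)) stop("all strata are empty")
  xmax <- max(vapply(nonempty, function(s) max(s$empirical_neglog_q), 0))
  ymax <- max(vapply(nonempty, function(s) max(s$nominal_neglog_p), 0))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = expression(-log[10](q)),
                 ylab = expression(-log[10](p)), main = main)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  cols <- seq_along(nonempty) + 1L
  for (i in seq_along(nonempty)) {
    s <- nonempty[[i]]
    graphics::lines(rev(s$empirical_neglog_q), rev(s$nominal_neglog_p),
                    col = cols[i], lwd = 1.5)
  }
  graphics::legend("topleft",
                   legend = sprintf("p_j <= %g", vapply(nonempty, `[[`,
                                                        0, "threshold")),
                   col = cols, lwd = 1.5, bty = "n")
  invisible(NULL)
}

#' Manhattan plot of -log10 FDR values
#'
#' @param md Data frame from [manhattan_data()].
#' @param alpha Significance line (default 0.05, drawn at
#'   `-log10(alpha) ~ 1.3`).
#' @param main Plot title.
#' @return `NULL`, invisibly.
#' @export
plot_manhattan <- function(md, alpha = 0.05, main = "Conditional Manhattan") {
  col <- (chrom_rank(md$chrom) %% 2L) + 1L
  graphics::plot(md$x, md$neglog_fdr, pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[col],
                 xlab = "genomic position", ylab = expression(-log[10](FDR)),
                 main = main, xaxt = "n")
  graphics::abline(h = -log10(alpha), col = "red")
  invisible(NULL)
}
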