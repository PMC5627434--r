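#' Per-sample density plot of log2 expression
#'
#' Overlaid kernel densities of `log2(count + offset)` per sample, colored
#' by an optional grouping — the standard view of how count distributions
#' (and their zero spikes) differ across tissues before and after
#' normalization.
#'
#' @param expr an `ExpressionExperiment`.
#' @param assay_name matrix to plot: `"counts"` or an assay name.
#' @param groups optional per-sample labels used for colors (defaults to
#'   `merged_group` when populated).
#' @param transform_offset pseudo-count for the log transform.
#' @param ... passed to [graphics::plot()].
#' @export
plot_expression_density <- function(expr, assay_name = "counts",
                                    groups = NULL, transform_offset = 1, ...) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  m <- if (assay_name == "counts") expr$counts else assay(expr, assay_name)
  lm <- log_transform(m, transform_offset)
  if (is.null(groups)) {
    mg <- expr$sample_table$merged_group
    groups <- if (all(is.na(mg))) rep("all", ncol(m)) else mg
  }
  f <- factor(groups)
  dens <- apply(lm, 2, stats::density)
  xr <- range(vapply(dens, function(d) range(d$x), numeric(2)))
  yr <- range(vapply(dens, function(d) range(d$y), numeric(2)))
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = sprintf("log2(value + %g)", transform_offset),
                 ylab = "density", ...)
  for (j in seq_along(dens)) {
    graphics::lines(dens[[j]], col = as.integer(f)[j])
  }
  if (nlevels(f) > 1L) {
    graphics::legend("topright", legend = levels(f),
                     col = seq_len(nlevels(f)), lty = 1, bty = "n")
  }
  invisible(expr)
}
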