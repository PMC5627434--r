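#' Continuity-corrected log2 transform
#'
#' Elementwise `log2(x + offset)`. The offset defaults to 1 (`log2(x + 1)`),
#' the safer choice for distance computations on counts; `offset = 0.5` gives
#' the classical continuity correction and both presets are in common use.
#'
#' @param m non-negative numeric matrix.
#' @param offset positive pseudo-count added before taking logs.
#' @return matrix of the same shape.
#' @export
log_transform <- function(m, offset = 1) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("input must be numeric")
  if (any(m < 0, na.rm = TRUE)) stop("negative entries are not allowed")
  if (!is.numeric(offset) || length(offset) != 1L || offset <= 0) {
    stop("offset must be a positive scalar")
  }
  log2(m + offset)
}

#' Euclidean distances between samples
#'
#' Pairwise Euclidean distances between the *columns* (samples) of a
#' gene-by-sample matrix.
#'
#' @param m numeric matrix, genes in rows, samples in columns.
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
euclidean_distances <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m))) stop("non-finite entries in input matrix")
  d <- as.matrix(stats::dist(t(m), method = "euclidean"))
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Principal coordinate analysis (classical multidimensional scaling)
#'
#' Embeds samples from a distance matrix by Gower double-centering of
#' \eqn{-d^2/2} and eigendecomposition; coordinates are eigenvectors scaled
#' by the square roots of their (non-negative) eigenvalues, so Euclidean
#' input distances are reproduced exactly when all axes are retained.
#'
#' Axes are ordered by decreasing eigenvalue. Negative eigenvalues — possible
#' for non-Euclidean dissimilarities — contribute no coordinates and are
#' excluded from the variance-explained denominator (with a warning). Each
#' axis's sign is canonicalized so its largest-magnitude coordinate is
#' positive, making results reproducible across eigen-solvers.
#'
#' @param d symmetric distance matrix (or `dist` object) with zero diagonal.
#' @param n_axes number of axes to retain (default `n - 1`).
#' @return An `OrdinationResult`: list with `coordinates` (sample-by-axis),
#'   `eigenvalues` (all, non-increasing), `variance_explained` (per retained
#'   axis, fractions of the positive-eigenvalue total) and `n_axes_for_90pct`,
#'   the smallest number of axes whose cumulative variance fraction reaches
#'   90% — the conventional depth to which ordination plots should be
#'   inspected.
#' @export
pcoa <- function(d, n_axes = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  n <- nrow(d)
  if (n != ncol(d)) stop("distance matrix must be square")
  if (any(!is.finite(d))) stop("non-finite distances")
  if (any(abs(d - t(d)) > 1e-8)) stop("distance matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-8)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  n_axes <- n_axes %||% (n - 1L)
  if (n_axes > n - 1L) stop("n_axes must be at most n_samples - 1")
  n_axes <- max(1L, as.integer(n_axes))

  fit <- suppressWarnings(stats::cmdscale(d, k = n_axes, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- eig[eig > 1e-12 * max(abs(eig), 1e-300)]
  if (any(eig < -1e-8 * max(abs(eig)))) {
    warning("negative eigenvalues dropped (non-Euclidean dissimilarity); ",
            "variance fractions computed over positive eigenvalues only")
  }

  coords <- fit$points
  if (is.null(coords) || ncol(coords) == 0L) {
    # degenerate geometry: all samples coincide
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    return(structure(list(coordinates = coords, eigenvalues = eig,
                          variance_explained = 1,
                          n_axes_for_90pct = 1L),
                     class = "OrdinationResult"))
  }
  k <- ncol(coords)
  # canonical sign: largest-magnitude coordinate on each axis is positive
  for (a in seq_len(k)) {
    i <- which.max(abs(coords[, a]))
    if (coords[i, a] < 0) coords[, a] <- -coords[, a]
  }
  colnames(coords) <- paste0("Axis", seq_len(k))
  rownames(coords) <- rownames(d)

  ve <- eig[seq_len(k)] / sum(pos)
  frac <- cumsum(pos) / sum(pos)
  structure(
    list(coordinates = coords,
         eigenvalues = eig,
         variance_explained = ve,
         n_axes_for_90pct = as.integer(which(frac >= 0.90)[1])),
    class = "OrdinationResult"
  )
}

#' @export
print.OrdinationResult <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("PCoA ordination: %d samples, %d axes retained\n",
              nrow(x$coordinates), k))
  show <- utils::head(x$variance_explained, 5)
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * show), collapse = ", "),
      if (k > 5) "...\n" else "\n")
  cat(sprintf("  axes to reach 90%% of variance: %d\n", x$n_axes_for_90pct))
  invisible(x)
}

#' Ordination scatterplot
#'
#' @param x an `OrdinationResult`.
#' @param axes which two axes to plot.
#' @param labels optional per-sample grouping used for colors.
#' @param ... passed to [graphics::plot()].
#' @export
plot.OrdinationResult <- function(x, axes = c(1, 2), labels = NULL, ...) {
  co <- x$coordinates
  if (ncol(co) < 2L) co <- cbind(co, 0)
  f <- if (is.null(labels)) factor(rep(1, nrow(co))) else factor(labels)
  graphics::plot(co[, axes[1]], co[, axes[2]], col = as.integer(f), pch = 19,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1],
                                100 * x$variance_explained[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2],
                                100 * x$variance_explained[min(axes[2], length(x$variance_explained))]),
                 ...)
  if (!is.null(labels)) {
    graphics::legend("topright", legend = levels(f), col = seq_along(levels(f)),
                     pch = 19, bty = "n")
  }
  invisible(x)
}

#' Rank genes by expression variance
#'
#' Ranks genes by the unbiased sample variance of `log2(count + offset)`
#' across samples, descending, with ties broken by input gene order; used to
#' pick the most variable genes (conventionally 1000) before ordination of
#' sample subgroups.
#'
#' @param expr an `ExpressionExperiment`.
#' @param n number of gene ids to return (capped at the gene count).
#' @param transform_offset pseudo-count for the log transform; `NULL` ranks
#'   raw counts instead.
#' @return character vector of gene ids, most variable first.
#' @export
most_variable_genes <- function(expr, n = 1000, transform_offset = 1) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  if (!is.numeric(n) || n < 1) stop("n must be at least 1")
  m <- expr$counts
  if (!is.null(transform_offset)) m <- log_transform(m, transform_offset)
  v <- apply(m, 1, stats::var)
  v[is.na(v)] <- 0   # single-sample edge: no variance defined
  ord <- order(-v, seq_along(v))
  rownames(expr$counts)[utils::head(ord, min(n, length(v)))]
}
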