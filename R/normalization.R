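# Group-aware quantile normalization.
#
# All three normalizers share one mechanic: compute a target vector of sorted
# values per sample (a quantile reference), then map it back onto the genes
# through the sample's ranks, averaging the target over tied raw values so
# that the heavy zero ties of count data receive a single well-defined value.

# Place `target` (sorted ascending, length(x)) at the positions of x's order
# statistics; tied raw values get the mean of their targets.
map_to_ranks <- function(x, target) {
  y <- numeric(length(x))
  y[order(x)] <- target
  if (anyDuplicated(x)) y <- stats::ave(y, x, FUN = mean)
  y
}

new_quantile_reference <- function(values, scope) {
  structure(list(values = values, scope = scope), class = "QuantileReference")
}

new_normalization_result <- function(normalized, method, weights = NULL,
                                     global_reference = NULL,
                                     group_references = list(),
                                     group_column = NA_character_) {
  structure(list(normalized = normalized, method = method, weights = weights,
                 global_reference = global_reference,
                 group_references = group_references,
                 group_column = group_column),
            class = "NormalizationResult")
}

#' @export
print.NormalizationResult <- function(x, ...) {
  cat(sprintf("Normalization (%s): %d genes x %d samples\n",
              x$method, nrow(x$normalized), ncol(x$normalized)))
  if (length(x$group_references)) {
    cat("  group references:", paste(names(x$group_references), collapse = ", "), "\n")
  }
  if (!is.null(x$weights)) {
    cat(sprintf("  smoothing weights: median %.3f (range %.3f-%.3f)\n",
                stats::median(x$weights), min(x$weights), max(x$weights)))
  }
  invisible(x)
}

#' Full (global) quantile normalization
#'
#' Forces every sample's empirical distribution onto a common reference: the
#' reference value at rank k is the mean over samples of their k-th order
#' statistics, and each sample's value at rank k is replaced by it. Ties
#' within a sample receive the mean of the reference values at the tied ranks.
#'
#' @param m numeric gene-by-sample matrix.
#' @return a `NormalizationResult` (method `"quantile_global"`) whose
#'   `normalized` element is the normalized matrix and whose
#'   `global_reference` holds the mean-quantile reference.
#' @export
quantile_normalize <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(new_normalization_result(m, "quantile_global",
                                    global_reference = new_quantile_reference(sort(m[, 1]), "global")))
  }
  Q <- apply(m, 2, sort)
  ref <- rowMeans(Q)
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- map_to_ranks(m[, j], ref)
  dimnames(out) <- dimnames(m)
  new_normalization_result(out, "quantile_global",
                           global_reference = new_quantile_reference(ref, "global"))
}

#' Smooth (group-aware) quantile normalization
#'
#' Generalizes quantile normalization to heterogeneous cohorts: instead of
#' assuming all samples share one count distribution, it assumes only that
#' samples *within a phenotype group* do, and blends, at every quantile, the
#' global reference with the sample's group reference.
#'
#' With \eqn{Q(k,j)} the k-th order statistic of sample j, the global
#' reference \eqn{\bar q_k} is the mean over all samples and the group
#' reference \eqn{\bar q_{g,k}} the mean within group g. At each rank k the
#' total and between-group sums of squares
#' \deqn{SST_k = \sum_j (Q(k,j) - \bar q_k)^2, \quad
#'       SSB_k = \sum_g n_g (\bar q_{g,k} - \bar q_k)^2}
#' give a raw weight \eqn{\hat w_k = 1 - SSB_k / SST_k} (1 when
#' \eqn{SST_k = 0}), smoothed by a running median over a window of
#' `window_fraction` of the quantiles (forced odd) and clamped to \[0, 1\].
#' Sample j in group g receives \eqn{w_k \bar q_k + (1 - w_k) \bar q_{g,k}}
#' at rank k: quantiles at which groups agree are normalized globally
#' (weight near 1), quantiles dominated by between-group differences — e.g.
#' the zero spike of tissue-specific genes — keep their group's own
#' reference (weight near 0).
#'
#' @param m numeric gene-by-sample matrix.
#' @param groups per-sample group labels (length `ncol(m)`).
#' @param window_fraction running-median window as a fraction of the number
#'   of genes (default 0.05); `window_fraction = 0` (or a window of 1)
#'   disables smoothing.
#' @param weights optional fixed per-quantile weights overriding the
#'   SST/SSB construction (length `nrow(m)`, values in \[0, 1\]); forcing 1
#'   reproduces global, forcing 0 per-group quantile normalization.
#' @return a `NormalizationResult` (method `"qsmooth"`) with the normalized
#'   matrix, the per-quantile `weights`, the `global_reference` and one
#'   `group_references` entry per group.
#' @export
qsmooth_normalize <- function(m, groups, window_fraction = 0.05,
                              weights = NULL) {
  m <- as.matrix(m)
  groups <- check_groups(groups, m)
  ng <- nrow(m)
  Q <- apply(m, 2, sort)
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = ng)
  qbar <- rowMeans(Q)
  lv <- unique(groups)
  qbar_g <- vapply(lv, function(g) rowMeans(Q[, groups == g, drop = FALSE]),
                   numeric(ng))
  colnames(qbar_g) <- lv

  if (is.null(weights)) {
    sst <- rowSums((Q - qbar)^2)
    n_g <- vapply(lv, function(g) sum(groups == g), numeric(1))
    ssb <- as.numeric((qbar_g - qbar)^2 %*% n_g)
    w <- ifelse(sst == 0, 1, 1 - ssb / sst)
    window <- max(1L, round(window_fraction * ng))
    if (window %% 2L == 0L) window <- window + 1L
    if (window > 1L) w <- stats::runmed(w, window, endrule = "median")
    w <- pmin(1, pmax(0, w))
  } else {
    if (length(weights) != ng) stop("weights must have one value per gene")
    if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
    w <- weights
  }

  out <- m
  for (j in seq_len(ncol(m))) {
    target <- w * qbar + (1 - w) * qbar_g[, groups[j]]
    out[, j] <- map_to_ranks(m[, j], target)
  }
  dimnames(out) <- dimnames(m)
  refs <- lapply(lv, function(g) new_quantile_reference(qbar_g[, g],
                                                        paste0("group:", g)))
  names(refs) <- lv
  new_normalization_result(out, "qsmooth", weights = w,
                           global_reference = new_quantile_reference(qbar, "global"),
                           group_references = refs)
}

#' Full quantile normalization within each group
#'
#' Applies [quantile_normalize()] independently inside every phenotype group;
#' a singleton group is returned unchanged with a warning.
#'
#' @inheritParams qsmooth_normalize
#' @return a `NormalizationResult` (method `"quantile_per_group"`).
#' @export
quantile_normalize_per_group <- function(m, groups) {
  m <- as.matrix(m)
  groups <- check_groups(groups, m)
  out <- m
  refs <- list()
  for (g in unique(groups)) {
    jj <- which(groups == g)
    if (length(jj) == 1L) {
      warning("group '", g, "' has a single sample; left unchanged")
      refs[[g]] <- new_quantile_reference(sort(m[, jj]), paste0("group:", g))
      next
    }
    r <- quantile_normalize(m[, jj, drop = FALSE])
    out[, jj] <- r$normalized
    refs[[g]] <- new_quantile_reference(r$global_reference$values,
                                        paste0("group:", g))
  }
  new_normalization_result(out, "quantile_per_group", group_references = refs)
}

check_groups <- function(groups, m) {
  if (length(groups) != ncol(m)) {
    stop("groups must have one label per sample (column)")
  }
  groups <- as.character(groups)
  if (any(is.na(groups) | groups == "")) {
    stop("missing group label for sample(s): ",
         paste((colnames(m) %||% seq_len(ncol(m)))[is.na(groups) | groups == ""],
               collapse = ", "))
  }
  groups
}

#' Group-aware normalization of an experiment
#'
#' Runs smooth quantile normalization (or full quantile normalization within
#' each group) on the raw counts, using a sample-table column as the
#' phenotype grouping, and stores the result as the `"normalized"` assay.
#' Raw counts are preserved and the assay is always recomputed from them, so
#' re-running is idempotent.
#'
#' @param expr an `ExpressionExperiment` with `group_column` populated.
#' @param group_column sample-table column holding the phenotype groups
#'   (default `"merged_group"`).
#' @param method `"qsmooth"` or `"quantile_per_group"`.
#' @param window_fraction passed to [qsmooth_normalize()].
#' @return the experiment with a `"normalized"` assay added and the
#'   normalization recorded in provenance; the full `NormalizationResult` is
#'   attached as attribute `"normalization"`.
#' @export
normalize_tissue_aware <- function(expr, group_column = "merged_group",
                                   method = c("qsmooth", "quantile_per_group"),
                                   window_fraction = 0.05) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  method <- match.arg(method)
  g <- expr$sample_table[[group_column]]
  if (is.null(g)) stop("no sample-table column named '", group_column, "'")
  if (any(is.na(g) | g == "")) {
    stop("'", group_column, "' is not populated for sample(s): ",
         paste(colnames(expr$counts)[is.na(g) | g == ""], collapse = ", "))
  }
  res <- if (method == "qsmooth") {
    qsmooth_normalize(expr$counts, g, window_fraction = window_fraction)
  } else {
    quantile_normalize_per_group(expr$counts, g)
  }
  res$group_column <- group_column
  expr$assays[["normalized"]] <- res$normalized
  expr <- log_provenance(expr, "normalize_tissue_aware",
                         list(method = method, group_column = group_column,
                              window_fraction = window_fraction))
  attr(expr, "normalization") <- res
  expr
}

#' Reference-divergence diagnostic (per-sample RMSE)
#'
#' Measures how badly a quantile reference fits each sample: for sample j,
#' \deqn{RMSE_j = \sqrt{\mathrm{mean}_k\,(\log_2(Q(k,j)+c) - \log_2(ref_k+c))^2}}
#' where the reference is either the global mean-quantile vector or the
#' sample's own group's, both computed on the raw quantiles. Heterogeneous
#' cohorts show much larger divergence from the global reference than from
#' group references — the motivation for group-aware normalization.
#'
#' @param m non-negative gene-by-sample matrix (raw counts).
#' @param groups per-sample group labels (required when
#'   `reference_scope = "group"`).
#' @param reference_scope `"global"` or `"group"`.
#' @param transform_offset pseudo-count for the log transform.
#' @return named numeric vector of per-sample RMSE values (log2 units).
#' @export
reference_rmse <- function(m, groups = NULL,
                           reference_scope = c("global", "group"),
                           transform_offset = 1) {
  m <- as.matrix(m)
  reference_scope <- match.arg(reference_scope)
  if (any(m < 0)) stop("matrix must be non-negative")
  Q <- apply(m, 2, sort)
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = nrow(m))
  lQ <- log2(Q + transform_offset)
  if (reference_scope == "global") {
    ref <- log2(rowMeans(Q) + transform_offset)
    rmse <- sqrt(colMeans((lQ - ref)^2))
  } else {
    groups <- check_groups(groups, m)
    rmse <- numeric(ncol(m))
    for (g in unique(groups)) {
      jj <- which(groups == g)
      ref <- log2(rowMeans(Q[, jj, drop = FALSE]) + transform_offset)
      rmse[jj] <- sqrt(colMeans((lQ[, jj, drop = FALSE] - ref)^2))
    }
  }
  stats::setNames(rmse, colnames(m))
}
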