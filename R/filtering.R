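#' Counts per million
#'
#' Library-size-standardized abundance: each entry divided by its sample's
#' total count (column sum of the matrix *as passed in*), times 1e6.
#'
#' @param m non-negative count matrix, genes in rows.
#' @return matrix of CPM values, same shape.
#' @export
cpm <- function(m) {
  m <- as.matrix(m)
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(m)[zero] %||% which(zero), collapse = ", "))
  }
  sweep(m, 2, lib, "/") * 1e6
}

#' Tissue-aware minimum-sample threshold
#'
#' The low-expression filter's sample threshold under the tissue-aware rule:
#' half the size of the smallest phenotype group, kept as an exact (possibly
#' fractional) value and compared with `>=`. With the bundled multi-tissue
#' group sizes (smallest group 36 samples) this is 18.
#'
#' @param group_sizes named integer vector (or table) of per-group sample counts.
#' @return the threshold, in samples.
#' @export
min_samples_tissue_aware <- function(group_sizes) {
  group_sizes <- unclass(group_sizes)
  if (length(group_sizes) == 0L) stop("empty group map")
  if (any(group_sizes < 1)) stop("all group sizes must be at least 1")
  min(group_sizes) / 2
}

new_filter_result <- function(retained, removed, rule, cpm_threshold = NA_real_,
                              min_samples = NA_real_, group_column = NULL,
                              pass_count = NULL) {
  structure(list(retained_ids = retained, removed_ids = removed, rule = rule,
                 cpm_threshold = cpm_threshold, min_samples = min_samples,
                 group_column = group_column,
                 per_gene_pass_count = pass_count),
            class = "FilterResult")
}

#' @export
print.FilterResult <- function(x, ...) {
  cat(sprintf("Gene filter (%s): retained %d, removed %d\n",
              x$rule, length(x$retained_ids), length(x$removed_ids)))
  if (!is.na(x$min_samples)) {
    cat(sprintf("  rule: CPM >= %g in at least %g samples%s\n",
                x$cpm_threshold, x$min_samples,
                if (!is.null(x$group_column))
                  sprintf(" (smallest '%s' group / 2)", x$group_column) else ""))
  }
  invisible(x)
}

#' Filter lowly expressed genes (tissue-aware or tissue-agnostic)
#'
#' Keeps a gene iff its CPM reaches `cpm_threshold` in at least `min_samples`
#' samples, counting over *all* samples pooled. When `group_column` is given
#' (tissue-aware mode) `min_samples` defaults to half the size of the
#' smallest group, so a gene expressed consistently in even the smallest
#' tissue survives; without it (tissue-agnostic mode) the default is half of
#' all samples, which discards tissue-specific genes expressed only in small
#' groups. Library sizes for CPM are computed on the matrix as passed in.
#'
#' @param expr an `ExpressionExperiment`.
#' @param group_column sample-table column naming the phenotype groups
#'   (e.g. `"merged_group"`), or `NULL` for the tissue-agnostic rule.
#' @param cpm_threshold CPM value a sample must reach to count as expressing
#'   the gene (default 1).
#' @param min_samples override for the sample threshold (exact real, compared
#'   with `>=`); defaults as described above.
#' @return list with `experiment` (retained genes only) and `result`
#'   (a `FilterResult` recording the rule, thresholds and per-gene pass
#'   counts).
#' @export
filter_low_genes <- function(expr, group_column = NULL, cpm_threshold = 1,
                             min_samples = NULL) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  n <- ncol(expr$counts)
  if (!is.null(group_column)) {
    g <- as.character(expr$sample_table[[group_column]])
    if (is.null(expr$sample_table[[group_column]])) {
      stop("no sample-table column named '", group_column, "'")
    }
    if (any(is.na(g) | g == "")) {
      stop("empty '", group_column, "' label for sample(s): ",
           paste(colnames(expr$counts)[is.na(g) | g == ""], collapse = ", "))
    }
    rule <- "tissue-aware"
    if (is.null(min_samples)) min_samples <- min_samples_tissue_aware(table(g))
  } else {
    rule <- "tissue-agnostic"
    if (is.null(min_samples)) min_samples <- n / 2
  }
  if (min_samples > n) {
    warning("min_samples (", min_samples, ") exceeds the sample count (", n,
            "); every gene may be removed")
  }
  cm <- cpm(expr$counts)
  pass <- rowSums(cm >= cpm_threshold)
  keep <- pass >= min_samples
  gid <- rownames(expr$counts)
  out <- subset_experiment(expr, gene_ids = gid[keep])
  out$provenance[[length(out$provenance)]] <-
    list(name = "filter_low_genes",
         params = list(rule = rule, cpm_threshold = cpm_threshold,
                       min_samples = min_samples,
                       group_column = group_column %||% "<none>",
                       removed = sum(!keep)),
         timestamp = format(Sys.time(), usetz = TRUE))
  res <- new_filter_result(gid[keep], gid[!keep], rule, cpm_threshold,
                           min_samples, group_column,
                           stats::setNames(as.integer(pass), gid))
  list(experiment = out, result = res)
}

#' Filter genes by chromosome
#'
#' Removes (or keeps only) genes annotated to the given chromosomes, e.g.
#' excluding X, Y and MT before autosomal variance ranking, or keeping only Y
#' for the sex screen.
#'
#' @param expr an `ExpressionExperiment`.
#' @param chromosomes character vector of chromosome names (`"M"` accepted
#'   for `"MT"`).
#' @param mode `"remove"` (drop matching genes) or `"keep"` (drop the rest).
#' @return list with `experiment` and `result` (a `FilterResult`).
#' @export
filter_genes_by_chromosome <- function(expr, chromosomes,
                                       mode = c("remove", "keep")) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  mode <- match.arg(mode)
  chromosomes <- normalize_chromosome(chromosomes)
  hit <- expr$gene_table$chromosome %in% chromosomes
  keep <- if (mode == "remove") !hit else hit
  gid <- rownames(expr$counts)
  out <- subset_experiment(expr, gene_ids = gid[keep])
  out$provenance[[length(out$provenance)]] <-
    list(name = "filter_genes_by_chromosome",
         params = list(mode = mode, chromosomes = chromosomes,
                       removed = sum(!keep)),
         timestamp = format(Sys.time(), usetz = TRUE))
  list(experiment = out,
       result = new_filter_result(gid[keep], gid[!keep],
                                  paste0("chromosome-", mode)))
}

#' Remove genes with no counts in any sample
#'
#' @param expr an `ExpressionExperiment`.
#' @return list with `experiment` and `result` (a `FilterResult`).
#' @export
filter_missing_genes <- function(expr) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  keep <- rowSums(expr$counts) > 0
  gid <- rownames(expr$counts)
  out <- subset_experiment(expr, gene_ids = gid[keep])
  out$provenance[[length(out$provenance)]] <-
    list(name = "filter_missing_genes",
         params = list(removed = sum(!keep)),
         timestamp = format(Sys.time(), usetz = TRUE))
  list(experiment = out,
       result = new_filter_result(gid[keep], gid[!keep], "missing"))
}

#' Tally gene biotypes
#'
#' Counts and fractions of each gene biotype (protein coding, pseudogene,
#' ...), the summary used to compare what different filters retain.
#'
#' @param expr an `ExpressionExperiment`.
#' @return data frame with columns `biotype`, `count`, `fraction` (fractions
#'   sum to 1), sorted by decreasing count.
#' @export
biotype_summary <- function(expr) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  tab <- table(expr$gene_table$biotype)
  tab <- sort(tab, decreasing = TRUE)
  data.frame(biotype = names(tab), count = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
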