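#' Screen for sex (or other binary-label) misannotation
#'
#' Restricts the experiment to the genes of one chromosome (Y by default,
#' whose genes are expressed only in genetically male samples), log2-transforms
#' the counts, ordinates the samples by PCoA on Euclidean distances, and
#' partitions them into two clusters by 2-means on the first principal
#' coordinate (best of 10 restarts under a fixed internal seed). Each cluster
#' is assigned the majority annotated label among its non-unknown members;
#' samples whose annotation disagrees with their cluster's majority are
#' flagged. Samples labeled `"unknown"` are clustered but never flagged.
#'
#' The clustering rule makes the visual two-group separation operational and
#' automatable; the full ordination is returned so the call can always be
#' inspected by eye.
#'
#' @param expr an `ExpressionExperiment`.
#' @param label_column sample-table column holding the annotation to check
#'   (default `"sex"`); must have exactly two observed non-unknown levels.
#' @param chromosome chromosome whose genes carry the signal (`"Y"`; `"M"` is
#'   accepted for `"MT"`).
#' @param transform_offset pseudo-count for the log transform.
#' @param n_axes number of ordination axes to retain in the report.
#' @return A `MisannotationReport`: list with `samples` (per-sample data frame
#'   with `sample_id`, `annotated_label`, `assigned_cluster`,
#'   `cluster_majority_label`, `concordant`), `flagged_ids`, `ordination`, and
#'   `genes_used`.
#' @export
check_misannotation <- function(expr, label_column = "sex", chromosome = "Y",
                                transform_offset = 1, n_axes = 2) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  chromosome <- normalize_chromosome(chromosome)
  genes <- rownames(expr$counts)[expr$gene_table$chromosome == chromosome]
  if (length(genes) < 2L) {
    stop("cannot screen without marker genes: fewer than 2 genes annotated to chromosome ",
         chromosome)
  }
  if (ncol(expr$counts) < 4L) stop("need at least 4 samples to screen")
  labels <- as.character(expr$sample_table[[label_column]])
  if (is.null(expr$sample_table[[label_column]])) {
    stop("no sample-table column named '", label_column, "'")
  }
  labels[is.na(labels)] <- "unknown"
  lv <- sort(unique(labels[labels != "unknown"]))
  if (length(lv) != 2L) {
    stop("label column '", label_column, "' must have exactly 2 observed levels, found: ",
         paste(lv, collapse = ", "))
  }

  lm <- log_transform(expr$counts[genes, , drop = FALSE], transform_offset)
  d <- euclidean_distances(lm)
  sid <- colnames(expr$counts)

  if (max(d) < 1e-8) {
    warning("degenerate geometry: all samples are (near-)identical on chromosome ",
            chromosome, " genes; no samples flagged")
    ord <- pcoa(d, n_axes = 1)
    samples <- data.frame(sample_id = sid, annotated_label = labels,
                          assigned_cluster = 1L,
                          cluster_majority_label = NA_character_,
                          concordant = TRUE, stringsAsFactors = FALSE)
    return(structure(list(samples = samples, flagged_ids = character(0),
                          ordination = ord, genes_used = genes),
                     class = "MisannotationReport"))
  }

  ord <- pcoa(d, n_axes = min(n_axes, ncol(expr$counts) - 1L))
  ax1 <- ord$coordinates[, 1]
  km <- with_local_seed(607, stats::kmeans(matrix(ax1, ncol = 1), centers = 2,
                                           nstart = 10))
  cl <- km$cluster

  majority <- vapply(1:2, function(k) {
    obs <- labels[cl == k & labels != "unknown"]
    if (!length(obs)) return(NA_character_)
    tab <- sort(table(obs), decreasing = TRUE)
    names(tab)[1]
  }, character(1))

  concordant <- labels == "unknown" | is.na(majority[cl]) | labels == majority[cl]
  samples <- data.frame(sample_id = sid, annotated_label = labels,
                        assigned_cluster = cl,
                        cluster_majority_label = majority[cl],
                        concordant = concordant, stringsAsFactors = FALSE)
  structure(list(samples = samples,
                 flagged_ids = sid[!concordant],
                 ordination = ord, genes_used = genes),
            class = "MisannotationReport")
}

#' @export
print.MisannotationReport <- function(x, ...) {
  cat(sprintf("Misannotation screen: %d samples on %d marker genes\n",
              nrow(x$samples), length(x$genes_used)))
  if (length(x$flagged_ids)) {
    cat("  flagged:", paste(x$flagged_ids, collapse = ", "), "\n")
  } else {
    cat("  no discordant samples\n")
  }
  invisible(x)
}

#' Assess whether sub-sites of a body site should be merged
#'
#' Restricts to the samples of one major body site and to autosomal genes
#' (X, Y and mitochondrial genes excluded), takes the most variable genes on
#' the log2 scale, ordinates by PCoA with Euclidean distance, and scores the
#' separation of the annotated sub-sites as the mean silhouette width of the
#' sub-site labels in the plane of the first two principal coordinates.
#'
#' The recommendation operationalizes the visual merge-or-split call:
#' `merge` when the mean silhouette is below `low` (subgroups
#' indistinguishable), `keep_separate` above `high` (clear separation),
#' `inspect` in between.
#'
#' @param expr an `ExpressionExperiment`.
#' @param major_site value of `sample_table$major_site` selecting the samples.
#' @param n_top_genes number of most-variable genes to use (default 1000).
#' @param exclude_chromosomes chromosomes removed before ranking
#'   (default X, Y, MT).
#' @param transform_offset pseudo-count for the log transform.
#' @param low,high silhouette thresholds for the merge / keep-separate calls.
#' @return A `MergeAssessment`: list with `major_site`, `ordination`,
#'   `subgroup_labels`, `separation_score` (mean silhouette, in \[-1, 1\]) and
#'   `recommendation`.
#' @export
assess_merge <- function(expr, major_site, n_top_genes = 1000,
                         exclude_chromosomes = c("X", "Y", "MT"),
                         transform_offset = 1, low = 0.25, high = 0.5) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  sel <- expr$sample_table$major_site == major_site
  if (!any(sel)) stop("no samples with major_site '", major_site, "'")
  sub <- subset_experiment(expr, sample_ids = colnames(expr$counts)[sel])
  labs <- as.character(sub$sample_table$sub_site)
  lv <- unique(labs)
  if (length(lv) < 2L) stop("nothing to assess: single sub_site '", lv, "'")
  szs <- table(labs)
  if (any(szs < 3L)) {
    stop("each sub_site needs at least 3 samples; too small: ",
         paste(names(szs)[szs < 3L], collapse = ", "))
  }
  exclude_chromosomes <- normalize_chromosome(exclude_chromosomes)
  keep <- !(sub$gene_table$chromosome %in% exclude_chromosomes)
  sub <- subset_experiment(sub, gene_ids = rownames(sub$counts)[keep])
  top <- most_variable_genes(sub, n = n_top_genes,
                             transform_offset = transform_offset)
  sub <- subset_experiment(sub, gene_ids = top)

  lm <- log_transform(sub$counts, transform_offset)
  ord <- pcoa(euclidean_distances(lm),
              n_axes = min(10L, ncol(sub$counts) - 1L))
  co <- ord$coordinates[, seq_len(min(2L, ncol(ord$coordinates))), drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labs)), stats::dist(co))
  score <- mean(sil[, "sil_width"])
  rec <- if (score < low) "merge" else if (score > high) "keep_separate" else "inspect"

  structure(list(major_site = major_site, ordination = ord,
                 subgroup_labels = labs, separation_score = score,
                 recommendation = rec, thresholds = c(low = low, high = high),
                 genes_used = top),
            class = "MergeAssessment")
}

#' @export
print.MergeAssessment <- function(x, ...) {
  cat(sprintf("Merge assessment for '%s': %d samples, %d sub-sites\n",
              x$major_site, length(x$subgroup_labels),
              length(unique(x$subgroup_labels))))
  cat(sprintf("  mean silhouette separation: %.3f -> %s\n",
              x$separation_score, x$recommendation))
  invisible(x)
}

#' Assign merged group labels from a sub-site map
#'
#' Fills `sample_table$merged_group` according to a sub-site-to-group map,
#' e.g. the bundled multi-tissue map ([gtex_merge_map()]) that consolidates
#' 49 sampled sub-sites into 38 transcriptionally distinct tissues. Counts
#' are untouched; the operation is logged.
#'
#' @param expr an `ExpressionExperiment`.
#' @param merge_map either a named character vector (`sub_site -> group`) or
#'   a data frame with columns `sub_site` and `merged_group`.
#' @return the experiment with `merged_group` populated.
#' @export
apply_merge <- function(expr, merge_map) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  if (is.data.frame(merge_map)) {
    if (!all(c("sub_site", "merged_group") %in% names(merge_map))) {
      stop("merge_map data frame needs 'sub_site' and 'merged_group' columns")
    }
    mm <- stats::setNames(as.character(merge_map$merged_group),
                          as.character(merge_map$sub_site))
  } else {
    mm <- merge_map
  }
  ss <- as.character(expr$sample_table$sub_site)
  unmapped <- setdiff(unique(ss), names(mm))
  if (length(unmapped)) {
    stop("sub_site(s) missing from merge map: ", paste(unmapped, collapse = ", "))
  }
  expr$sample_table$merged_group <- unname(mm[ss])
  log_provenance(expr, "apply_merge",
                 list(n_groups = length(unique(expr$sample_table$merged_group))))
}

#' Remove samples flagged by a misannotation screen
#'
#' @param expr an `ExpressionExperiment`.
#' @param report a `MisannotationReport` (or a character vector of sample ids).
#' @return the experiment without the flagged samples.
#' @export
remove_flagged_samples <- function(expr, report) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  flagged <- if (inherits(report, "MisannotationReport")) report$flagged_ids else as.character(report)
  if (!length(flagged)) {
    return(log_provenance(expr, "remove_flagged_samples", list(n_removed = 0L)))
  }
  keep <- setdiff(colnames(expr$counts), flagged)
  if (!length(keep)) warning("all samples flagged; returning an empty-sample experiment")
  out <- subset_experiment(expr, sample_ids = keep)
  # replace the generic subset record with a purposeful one
  out$provenance[[length(out$provenance)]] <-
    list(name = "remove_flagged_samples",
         params = list(removed = flagged),
         timestamp = format(Sys.time(), usetz = TRUE))
  out
}
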