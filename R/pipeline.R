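#' Pipeline configuration
#'
#' Collects every stage toggle and parameter of [run_pipeline()] with the
#' conventional defaults (1000 most-variable genes, CPM threshold 1,
#' X/Y/MT exclusion, 5% smoothing window).
#'
#' @param sex_check run the sex-misannotation screen and drop flagged
#'   samples.
#' @param sex_chromosome marker chromosome for the screen.
#' @param sex_label_column sample-table column the screen checks.
#' @param merge_map optional sub-site to group map (data frame or named
#'   vector) applied before filtering; `NULL` uses each sample's `sub_site`
#'   as its own group when `merged_group` is unset.
#' @param filter_low run the low-expression gene filter.
#' @param filter_group_column grouping column for tissue-aware filtering;
#'   `NULL` switches to the tissue-agnostic rule.
#' @param cpm_threshold CPM threshold of the low-expression filter.
#' @param filter_missing drop all-zero genes first.
#' @param normalize_method `"qsmooth"`, `"quantile_per_group"`, or `"none"`.
#' @param window_fraction qsmooth running-median window fraction.
#' @param transform_offset pseudo-count shared by the log transforms.
#' @param n_top_genes most-variable gene count for merge assessment.
#' @param seed integer seed for any stage randomness.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(sex_check = TRUE, sex_chromosome = "Y",
                            sex_label_column = "sex",
                            merge_map = NULL,
                            filter_low = TRUE,
                            filter_group_column = "merged_group",
                            cpm_threshold = 1,
                            filter_missing = TRUE,
                            normalize_method = c("qsmooth", "quantile_per_group", "none"),
                            window_fraction = 0.05,
                            transform_offset = 1,
                            n_top_genes = 1000,
                            seed = 1) {
  structure(list(sex_check = sex_check, sex_chromosome = sex_chromosome,
                 sex_label_column = sex_label_column, merge_map = merge_map,
                 filter_low = filter_low,
                 filter_group_column = filter_group_column,
                 cpm_threshold = cpm_threshold,
                 filter_missing = filter_missing,
                 normalize_method = match.arg(normalize_method),
                 window_fraction = window_fraction,
                 transform_offset = transform_offset,
                 n_top_genes = n_top_genes, seed = seed),
            class = "PipelineConfig")
}

count_stage <- function(summary, stage, expr) {
  grp <- expr$sample_table$merged_group
  n_groups <- if (all(is.na(grp))) length(unique(expr$sample_table$sub_site))
              else length(unique(grp[!is.na(grp)]))
  rbind(summary, data.frame(stage = stage,
                            n_samples = ncol(expr$counts),
                            n_genes = nrow(expr$counts),
                            n_groups = n_groups,
                            stringsAsFactors = FALSE))
}

#' Run the full preprocessing pipeline
#'
#' Chains the stages in their canonical order — sex-misannotation screen
#' (with removal of flagged samples), merge-map application, removal of
#' all-zero genes, low-expression filtering, normalization — and returns the
#' processed experiment together with a per-stage summary of sample, gene
#' and group counts (the pipeline's audit trail).
#'
#' @param expr an `ExpressionExperiment`.
#' @param config a [pipeline_config()].
#' @return list with `experiment` (processed), `summary` (data frame: stage,
#'   n_samples, n_genes, n_groups after each stage), `sex_report` (the
#'   `MisannotationReport`, or `NULL` when the stage is off) and
#'   `filter_result`.
#' @export
run_pipeline <- function(expr, config = pipeline_config()) {
  stopifnot(inherits(expr, "ExpressionExperiment"),
            inherits(config, "PipelineConfig"))
  summary <- count_stage(NULL, "input", expr)
  sex_report <- NULL
  filter_result <- NULL

  if (isTRUE(config$sex_check)) {
    sex_report <- check_misannotation(expr,
                                      label_column = config$sex_label_column,
                                      chromosome = config$sex_chromosome,
                                      transform_offset = config$transform_offset)
    expr <- remove_flagged_samples(expr, sex_report)
    summary <- count_stage(summary, "sex_check", expr)
  }

  if (!is.null(config$merge_map)) {
    expr <- apply_merge(expr, config$merge_map)
  } else if (all(is.na(expr$sample_table$merged_group))) {
    expr$sample_table$merged_group <- expr$sample_table$sub_site
    expr <- log_provenance(expr, "apply_merge",
                           list(note = "identity map: sub_site as group"))
  }
  summary <- count_stage(summary, "merge", expr)

  if (isTRUE(config$filter_missing)) {
    f <- filter_missing_genes(expr)
    expr <- f$experiment
    summary <- count_stage(summary, "filter_missing", expr)
  }
  if (isTRUE(config$filter_low)) {
    f <- filter_low_genes(expr, group_column = config$filter_group_column,
                          cpm_threshold = config$cpm_threshold)
    expr <- f$experiment
    filter_result <- f$result
    summary <- count_stage(summary, "filter_low", expr)
  }

  if (config$normalize_method != "none") {
    expr <- normalize_tissue_aware(expr, group_column = "merged_group",
                                   method = config$normalize_method,
                                   window_fraction = config$window_fraction)
    summary <- count_stage(summary, "normalize", expr)
  }

  list(experiment = expr, summary = summary,
       sex_report = sex_report, filter_result = filter_result)
}
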