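# Bundled multi-tissue reference tables: the canonical consolidation of 49
# sampled body sub-sites into 38 transcriptionally distinct tissue groups,
# with the per-group sample sizes of the cohort it was derived from.

#' Bundled sub-site to tissue-group merge map
#'
#' The reference mapping from 49 sampled body sub-sites to the 38 merged
#' tissue groups that survive ordination-based merge assessment (e.g. the
#' two skin sampling sites merge; cerebellum and cerebellar hemisphere merge;
#' the arterial and esophageal sub-sites stay separate). Suitable as the
#' `merge_map` argument of [apply_merge()].
#'
#' @return data frame with columns `sub_site`, `merged_group`, `abbreviation`.
#' @export
gtex_merge_map <- function() {
  utils::read.delim(system.file("extdata", "gtex_merge_map.tsv",
                                package = "tanorm", mustWork = TRUE),
                    sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled per-tissue-group sample sizes
#'
#' Sample counts of the 38 merged tissue groups (9435 samples in total;
#' smallest group: kidney cortex, 36 samples). These sizes drive the
#' tissue-aware filtering threshold: [min_samples_tissue_aware()] on this
#' table gives 18.
#'
#' @return data frame with columns `merged_group`, `abbreviation`,
#'   `n_samples`.
#' @export
gtex_group_sizes <- function() {
  utils::read.delim(system.file("extdata", "gtex_group_sizes.tsv",
                                package = "tanorm", mustWork = TRUE),
                    sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
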