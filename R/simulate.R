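# Synthetic multi-group count experiments with known ground truth.
#
# The generator emulates the data properties every pipeline stage relies on:
# several phenotype groups with group-specific expressed gene sets (a heavy
# zero spike outside the expressing group), negative-binomial counts with
# per-sample library-size variation, Y-chromosome genes expressed only in
# genetically male samples, and optionally injected sex-misannotated samples
# (the recorded sex is flipped; the molecular profile is untouched).

# Deterministic substream per sample: the global seed fixes the experiment
# design, and each sample's counts are drawn under seed f(seed, j), so the
# output is independent of generation order.
sample_substream_seed <- function(seed, j) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(j)
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a multi-group expression experiment with known truth
#'
#' Baseline gene means are drawn log-normal. Each group receives a disjoint
#' set of group-specific ("tissue-specific") genes whose mean is shifted up
#' by `group_shift_log2` within the group and set near zero (mean 0.05, so
#' the CPM boundary is exercised rather than structurally zero) outside it.
#' `y_gene_count` genes are annotated to chromosome Y and expressed only in
#' genetically male samples. Counts are negative binomial
#' (variance \eqn{\mu + \phi\mu^2}) with per-sample library-size factors
#' drawn uniformly from `library_size_range`. A fraction
#' `misannotation_rate` of samples have their *recorded* sex flipped while
#' their expression profile keeps the true sex — the ground truth for the
#' misannotation screen.
#'
#' Output is fully deterministic given `seed`; each sample is drawn from its
#' own seed-derived substream.
#'
#' @param n_groups number of phenotype groups.
#' @param samples_per_group samples in each group.
#' @param n_genes total genes.
#' @param tissue_specific_fraction fraction of genes made group-specific,
#'   split evenly across groups (default 0.1).
#' @param y_gene_count number of Y-chromosome marker genes (default 20).
#' @param misannotation_rate fraction of samples whose recorded sex is
#'   flipped (default 0).
#' @param group_shift_log2 log2 up-shift of a group-specific gene inside its
#'   group (default 2).
#' @param y_shift_log2 log2 difference of Y-gene means between male and
#'   female profiles (default 10, a strong sex signal).
#' @param y_base_mean Y-gene mean in female profiles (default 0.05, the
#'   near-zero floor); male profiles get `y_base_mean * 2^y_shift_log2`.
#' @param nb_dispersion negative-binomial dispersion \eqn{\phi} (default 0.5);
#'   0 gives Poisson counts.
#' @param library_size_range range of uniform per-sample library-size
#'   factors (default `c(0.7, 1.3)`).
#' @param seed integer seed.
#' @return list with `experiment` (an `ExpressionExperiment`) and `truth`
#'   (a `SimulationTruth`: seed, per-sample `group_of` and `true_sex`,
#'   `injected_misannotations`, `tissue_specific_genes` per group, `y_genes`,
#'   the gene-by-group `nb_mean` matrix, `nb_dispersion`,
#'   `library_size_factors`).
#' @export
simulate_experiment <- function(n_groups = 3, samples_per_group = 10,
                                n_genes = 500,
                                tissue_specific_fraction = 0.1,
                                y_gene_count = 20,
                                misannotation_rate = 0,
                                group_shift_log2 = 2,
                                y_shift_log2 = 10,
                                y_base_mean = 0.05,
                                nb_dispersion = 0.5,
                                library_size_range = c(0.7, 1.3),
                                seed = 1) {
  stopifnot(n_groups >= 1, samples_per_group >= 1, n_genes >= 1,
            tissue_specific_fraction >= 0, tissue_specific_fraction <= 1,
            misannotation_rate >= 0, misannotation_rate <= 1,
            y_gene_count >= 0, y_gene_count < n_genes)
  n_samples <- n_groups * samples_per_group
  group_names <- sprintf("group%02d", seq_len(n_groups))
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))

  # --- experiment design (global stream) ---
  design <- with_local_seed(as.integer(seed) %% 1000003L, {
    baseline <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
    y_idx <- if (y_gene_count > 0) seq(n_genes - y_gene_count + 1L, n_genes) else integer(0)
    n_ts_total <- round(tissue_specific_fraction * n_genes)
    if (n_ts_total + y_gene_count > n_genes) {
      stop("tissue-specific and Y gene sets cannot exceed the gene count")
    }
    per_group <- n_ts_total %/% n_groups
    ts_idx <- lapply(seq_len(n_groups), function(g) {
      if (per_group == 0) return(integer(0))
      seq((g - 1L) * per_group + 1L, g * per_group)
    })
    biotype <- sample(c("protein_coding", "pseudogene", "lincRNA"),
                      n_genes, replace = TRUE, prob = c(0.6, 0.11, 0.29))
    chromosome <- rep(as.character(rep_len(1:22, n_genes)))
    chromosome[y_idx] <- "Y"
    group_of <- rep(group_names, each = samples_per_group)
    true_sex <- rep_len(c("male", "female"), n_samples)
    n_flip <- round(misannotation_rate * n_samples)
    flipped <- if (n_flip > 0) sort(sample(n_samples, n_flip)) else integer(0)
    list(baseline = baseline, y_idx = y_idx, ts_idx = ts_idx,
         biotype = biotype, chromosome = chromosome, group_of = group_of,
         true_sex = true_sex, flipped = flipped)
  })

  nb_mean <- matrix(design$baseline, n_genes, n_groups,
                    dimnames = list(gene_ids, group_names))
  for (g in seq_len(n_groups)) {
    idx <- design$ts_idx[[g]]
    if (length(idx)) {
      nb_mean[idx, g] <- design$baseline[idx] * 2^group_shift_log2
      nb_mean[idx, -g] <- 0.05
    }
  }
  # Y genes: the per-group column holds the male-profile mean; female
  # profiles use the base (near-zero) floor.
  y_floor <- y_base_mean
  if (length(design$y_idx)) {
    nb_mean[design$y_idx, ] <- y_floor * 2^y_shift_log2
  }

  counts <- matrix(0, n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
  lib_factors <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    g <- match(design$group_of[j], group_names)
    mu <- nb_mean[, g]
    if (length(design$y_idx) && design$true_sex[j] != "male") {
      mu[design$y_idx] <- y_floor
    }
    counts[, j] <- with_local_seed(sample_substream_seed(seed, j), {
      lf <- stats::runif(1, library_size_range[1], library_size_range[2])
      lib_factors[j] <- lf
      rnbinom_mu(n_genes, mu * lf, nb_dispersion)
    })
  }

  recorded_sex <- design$true_sex
  recorded_sex[design$flipped] <- ifelse(design$true_sex[design$flipped] == "male",
                                         "female", "male")

  gene_table <- data.frame(gene_id = gene_ids, chromosome = design$chromosome,
                           biotype = design$biotype, symbol = NA_character_,
                           stringsAsFactors = FALSE)
  sample_table <- data.frame(sample_id = sample_ids,
                             donor_id = sprintf("D%04d", seq_len(n_samples)),
                             sex = recorded_sex,
                             major_site = design$group_of,
                             sub_site = design$group_of,
                             merged_group = design$group_of,
                             stringsAsFactors = FALSE)
  ee <- expression_experiment(counts, gene_table, sample_table)
  ee <- log_provenance(ee, "simulate_experiment",
                       list(n_groups = n_groups,
                            samples_per_group = samples_per_group,
                            n_genes = n_genes, seed = seed))

  ts_sets <- lapply(design$ts_idx, function(i) gene_ids[i])
  names(ts_sets) <- group_names
  truth <- structure(
    list(seed = seed,
         group_of = stats::setNames(design$group_of, sample_ids),
         true_sex = stats::setNames(design$true_sex, sample_ids),
         injected_misannotations = sample_ids[design$flipped],
         tissue_specific_genes = ts_sets,
         y_genes = gene_ids[design$y_idx],
         nb_mean = nb_mean,
         nb_dispersion = nb_dispersion,
         library_size_range = library_size_range,
         library_size_factors = stats::setNames(lib_factors, sample_ids)),
    class = "SimulationTruth")
  list(experiment = ee, truth = truth)
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf("Simulation truth (seed %s): %d samples, %d genes\n",
              format(x$seed), length(x$group_of), nrow(x$nb_mean)))
  cat(sprintf("  groups: %s\n", paste(colnames(x$nb_mean), collapse = ", ")))
  cat(sprintf("  injected sex misannotations: %d\n",
              length(x$injected_misannotations)))
  invisible(x)
}

#' Simulate two sub-sites of one body site with a controllable shift
#'
#' Test bed for the merge assessment: two sub-sites under one major site
#' whose count distributions differ by a mean shift of `shift_log2` (log2
#' units) in a stated fraction of genes. `shift_log2 = 0` makes the
#' sub-sites identically distributed (the merge case); a large shift makes
#' them clearly separable (the keep-separate case).
#'
#' @param shift_log2 log2 mean shift applied to the second sub-site's
#'   shifted genes (>= 0).
#' @param samples_per_subsite samples per sub-site (default 12).
#' @param n_genes total genes (default 400).
#' @param shifted_fraction fraction of genes shifted (default 0.3).
#' @param nb_dispersion negative-binomial dispersion (default 0.5).
#' @param library_size_range per-sample library-size factor range.
#' @param seed integer seed.
#' @return list with `experiment` and `truth`; the truth's
#'   `tissue_specific_genes` records the shifted gene set under the second
#'   sub-site's name.
#' @export
simulate_mergeable_subsites <- function(shift_log2,
                                        samples_per_subsite = 12,
                                        n_genes = 400,
                                        shifted_fraction = 0.3,
                                        nb_dispersion = 0.5,
                                        library_size_range = c(0.7, 1.3),
                                        seed = 1) {
  stopifnot(shift_log2 >= 0, samples_per_subsite >= 1, n_genes >= 1,
            shifted_fraction >= 0, shifted_fraction <= 1)
  n_samples <- 2L * samples_per_subsite
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  subsite <- rep(c("siteA", "siteB"), each = samples_per_subsite)

  design <- with_local_seed(as.integer(seed) %% 1000003L, {
    baseline <- stats::rlnorm(n_genes, meanlog = log(50), sdlog = 1.2)
    n_shift <- round(shifted_fraction * n_genes)
    shifted <- if (n_shift > 0) sort(sample(n_genes, n_shift)) else integer(0)
    list(baseline = baseline, shifted = shifted)
  })
  mean_a <- design$baseline
  mean_b <- design$baseline
  mean_b[design$shifted] <- mean_b[design$shifted] * 2^shift_log2

  counts <- matrix(0, n_genes, n_samples, dimnames = list(gene_ids, sample_ids))
  lib_factors <- numeric(n_samples)
  for (j in seq_len(n_samples)) {
    mu <- if (subsite[j] == "siteA") mean_a else mean_b
    counts[, j] <- with_local_seed(sample_substream_seed(seed, j), {
      lf <- stats::runif(1, library_size_range[1], library_size_range[2])
      lib_factors[j] <- lf
      rnbinom_mu(n_genes, mu * lf, nb_dispersion)
    })
  }

  gene_table <- data.frame(gene_id = gene_ids,
                           chromosome = as.character(rep_len(1:22, n_genes)),
                           biotype = "protein_coding", symbol = NA_character_,
                           stringsAsFactors = FALSE)
  sample_table <- data.frame(sample_id = sample_ids,
                             donor_id = sprintf("D%04d", seq_len(n_samples)),
                             sex = rep_len(c("male", "female"), n_samples),
                             major_site = "site",
                             sub_site = subsite,
                             stringsAsFactors = FALSE)
  ee <- expression_experiment(counts, gene_table, sample_table)
  ee <- log_provenance(ee, "simulate_mergeable_subsites",
                       list(shift_log2 = shift_log2, n_genes = n_genes,
                            seed = seed))
  truth <- structure(
    list(seed = seed,
         group_of = stats::setNames(subsite, sample_ids),
         true_sex = stats::setNames(sample_table$sex, sample_ids),
         injected_misannotations = character(0),
         tissue_specific_genes = list(siteB = gene_ids[design$shifted]),
         y_genes = character(0),
         nb_mean = matrix(c(mean_a, mean_b), ncol = 2,
                          dimnames = list(gene_ids, c("siteA", "siteB"))),
         nb_dispersion = nb_dispersion,
         library_size_range = library_size_range,
         library_size_factors = stats::setNames(lib_factors, sample_ids)),
    class = "SimulationTruth")
  list(experiment = ee, truth = truth)
}
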