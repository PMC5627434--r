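test_that("an injected sex swap is flagged exactly, across seeds and sample orders", {
  for (s in 1:8) {
    sim <- simulate_experiment(n_groups = 1, samples_per_group = 20,
                               n_genes = 200, y_gene_count = 15,
                               misannotation_rate = 0.05, seed = s)
    rep <- check_misannotation(sim$experiment)
    expect_setequal(rep$flagged_ids, sim$truth$injected_misannotations)
    expect_identical(sort(rep$samples$sample_id[!rep$samples$concordant]),
                     sort(rep$flagged_ids))

    # invariance to sample permutation
    perm <- sample(colnames(sim$experiment$counts))
    rep2 <- check_misannotation(subset_experiment(sim$experiment,
                                                  sample_ids = perm))
    expect_setequal(rep2$flagged_ids, rep$flagged_ids)
  }
})

test_that("unknown-sex samples are clustered but never flagged", {
  sim <- simulate_experiment(n_groups = 1, samples_per_group = 16,
                             n_genes = 150, y_gene_count = 10, seed = 4)
  ee <- sim$experiment
  ee$sample_table$sex[1:3] <- "unknown"
  rep <- check_misannotation(ee)
  expect_false(any(rep$samples$sample_id[1:3] %in% rep$flagged_ids))
  expect_true(all(rep$samples$assigned_cluster[1:3] %in% 1:2))
})

test_that("degenerate geometry and missing marker genes are handled explicitly", {
  counts <- matrix(5, 6, 6, dimnames = list(paste0("g", 1:6), paste0("s", 1:6)))
  ee <- expression_experiment(
    counts,
    data.frame(gene_id = paste0("g", 1:6), chromosome = c("Y", "Y", "Y", 1, 1, 1)),
    data.frame(sample_id = paste0("s", 1:6), donor_id = paste0("d", 1:6),
               sex = rep(c("male", "female"), 3), major_site = "m",
               sub_site = "m"))
  expect_warning(rep <- check_misannotation(ee), "degenerate")
  expect_length(rep$flagged_ids, 0)

  expect_error(check_misannotation(ee, chromosome = "Z"), "marker genes")
})

test_that("merge assessment separates distinct sub-sites and merges identical ones", {
  m0 <- simulate_mergeable_subsites(0, samples_per_subsite = 12,
                                    n_genes = 300, seed = 7)
  a0 <- assess_merge(m0$experiment, "site", n_top_genes = 200)
  expect_lt(a0$separation_score, 0.25)
  expect_identical(a0$recommendation, "merge")

  m4 <- simulate_mergeable_subsites(4, samples_per_subsite = 12,
                                    n_genes = 300, seed = 7)
  a4 <- assess_merge(m4$experiment, "site", n_top_genes = 200)
  expect_gt(a4$separation_score, 0.5)
  expect_identical(a4$recommendation, "keep_separate")

  # a duplicated sub-site (same samples relabeled) shows no separation
  ee <- m0$experiment
  ee$sample_table$sub_site <- rep(c("dupA", "dupB"), length.out = ncol(ee$counts))
  ad <- assess_merge(ee, "site", n_top_genes = 200)
  expect_lt(ad$separation_score, 0.25)
})

test_that("merge recommendation is monotone in the planted shift", {
  shifts <- c(0, 1, 2, 3, 4)
  scores <- vapply(shifts, function(sh) {
    m <- simulate_mergeable_subsites(sh, samples_per_subsite = 10,
                                     n_genes = 250, seed = 11)
    assess_merge(m$experiment, "site", n_top_genes = 150)$separation_score
  }, numeric(1))
  ranks <- c(merge = 1, inspect = 2, keep_separate = 3)
  recs <- ranks[ifelse(scores < 0.25, "merge",
                       ifelse(scores > 0.5, "keep_separate", "inspect"))]
  expect_true(all(diff(recs) >= 0))
  expect_identical(unname(recs[1]), 1)  # shift 0 merges
  expect_identical(unname(recs[5]), 3)  # shift 4 stays separate
})

test_that("merge assessment enforces its preconditions", {
  m <- simulate_mergeable_subsites(0, samples_per_subsite = 6, n_genes = 100,
                                   seed = 2)
  one <- m$experiment
  one$sample_table$sub_site <- "only"
  expect_error(assess_merge(one, "site"), "nothing to assess")
  expect_error(assess_merge(m$experiment, "no_such_site"), "no samples")
})

test_that("apply_merge fills merged_group; the bundled map yields 38 groups", {
  ee <- make_toy_experiment()
  idm <- setNames(unique(ee$sample_table$sub_site),
                  unique(ee$sample_table$sub_site))
  out <- apply_merge(ee, idm)
  expect_identical(out$sample_table$merged_group, ee$sample_table$sub_site)

  mm <- gtex_merge_map()
  n <- nrow(mm)
  counts <- matrix(rpois(2 * n, 10), 2, n,
                   dimnames = list(c("gA", "gB"), sprintf("s%02d", 1:n)))
  ee49 <- expression_experiment(
    counts, data.frame(gene_id = c("gA", "gB")),
    data.frame(sample_id = sprintf("s%02d", 1:n), donor_id = "d",
               sex = "unknown", major_site = "x", sub_site = mm$sub_site))
  merged <- apply_merge(ee49, mm)
  expect_identical(length(unique(merged$sample_table$merged_group)), 38L)

  expect_error(apply_merge(ee, idm[-1]), "missing from merge map")
})

test_that("flagged-sample removal drops exactly the flagged samples", {
  sim <- simulate_experiment(n_groups = 1, samples_per_group = 20,
                             n_genes = 150, y_gene_count = 10,
                             misannotation_rate = 0.05, seed = 9)
  rep <- check_misannotation(sim$experiment)
  expect_length(rep$flagged_ids, 1)
  out <- remove_flagged_samples(sim$experiment, rep)
  expect_identical(ncol(out$counts), 19L)
  expect_false(rep$flagged_ids %in% colnames(out$counts))

  same <- remove_flagged_samples(sim$experiment, character(0))
  expect_identical(same$counts, sim$experiment$counts)

  expect_warning(
    empty <- remove_flagged_samples(sim$experiment,
                                    colnames(sim$experiment$counts)),
    "all samples")
  expect_identical(ncol(empty$counts), 0L)
})
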