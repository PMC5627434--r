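test_that("cpm matches the definition, a brute-force oracle, and edgeR", {
  m <- matrix(c(100, 999900, 0, 1e6), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(cpm(m)["g1", "s1"], 100)
  expect_equal(unname(cpm(m)["g1", "s2"]), 0)

  set.seed(61)
  m <- matrix(rpois(12, 50), 4, 3,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  expect_equal(cpm(m), brute_cpm(m))
  expect_equal(unname(cpm(m)), unname(as.matrix(edgeR::cpm(m))),
               tolerance = 1e-12)

  zero <- m
  zero[, 2] <- 0
  expect_error(cpm(zero), "s2")
})

test_that("the tissue-aware sample threshold is half the smallest group, unrounded", {
  gs <- gtex_group_sizes()
  expect_equal(min_samples_tissue_aware(setNames(gs$n_samples, gs$merged_group)),
               18)
  expect_equal(min_samples_tissue_aware(c(a = 7)), 3.5)
  expect_equal(min_samples_tissue_aware(c(a = 10, b = 4)), 2)
  expect_error(min_samples_tissue_aware(integer(0)), "empty")
})

test_that("low-expression filtering matches the brute-force per-gene loop in both modes", {
  set.seed(71)
  for (rep in 1:10) {
    counts <- matrix(rnbinom(50 * 30, mu = 2^runif(50, -3, 8), size = 2),
                     50, 30, dimnames = list(sprintf("g%02d", 1:50),
                                             sprintf("s%02d", 1:30)))
    counts[rowSums(counts) == 0, 1] <- 1   # keep library sizes positive
    groups <- rep(c("a", "b", "c"), c(5, 10, 15))
    ee <- expression_experiment(
      counts, data.frame(gene_id = rownames(counts)),
      data.frame(sample_id = colnames(counts), donor_id = "d",
                 sex = "unknown", major_site = "m", sub_site = groups,
                 merged_group = groups))

    aware <- filter_low_genes(ee, group_column = "merged_group")
    expect_identical(aware$result$min_samples, 2.5)  # min group 5 / 2
    expect_identical(aware$result$retained_ids,
                     rownames(counts)[brute_low_filter(counts, 1, 2.5)])

    agn <- filter_low_genes(ee, group_column = NULL)
    expect_identical(agn$result$min_samples, 15)
    expect_identical(agn$result$retained_ids,
                     rownames(counts)[brute_low_filter(counts, 1, 15)])

    # tissue-aware retains a superset when its threshold is lower
    expect_true(all(agn$result$retained_ids %in% aware$result$retained_ids))

    # permutation of samples changes nothing
    perm <- sample(colnames(counts))
    aware_p <- filter_low_genes(subset_experiment(ee, sample_ids = perm),
                                group_column = "merged_group")
    expect_identical(aware_p$result$retained_ids, aware$result$retained_ids)
  }
})

test_that("pass counts sit on the >= boundary exactly", {
  # 6 samples, equal library sizes: CPM >= 1 iff count >= 1 here
  counts <- rbind(two = c(1, 1, 0, 0, 0, 0),
                  one = c(1, 0, 0, 0, 0, 0),
                  all6 = rep(1, 6),
                  zero = rep(0, 6))
  counts <- counts * 1  # doubles
  filler <- 1e6 - colSums(counts)  # pad every library size to exactly 1e6
  m <- rbind(counts, filler = filler)
  colnames(m) <- paste0("s", 1:6)
  ee <- expression_experiment(
    m, data.frame(gene_id = rownames(m)),
    data.frame(sample_id = colnames(m), donor_id = "d", sex = "unknown",
               major_site = "m", sub_site = rep(c("x", "y"), each = 3),
               merged_group = rep(c("x", "y"), each = 3)))
  f <- filter_low_genes(ee, group_column = "merged_group")  # min_samples 1.5
  expect_true("two" %in% f$result$retained_ids)    # 2 >= 1.5
  expect_false("one" %in% f$result$retained_ids)   # 1 < 1.5
  expect_true("all6" %in% f$result$retained_ids)
  expect_false("zero" %in% f$result$retained_ids)
  expect_identical(unname(f$result$per_gene_pass_count[c("two", "one", "zero")]),
                   c(2L, 1L, 0L))
})

test_that("a planted group-specific gene survives tissue-aware but not tissue-agnostic filtering", {
  # one group of 6 in a cohort of 30: specific gene expressed only there
  n <- 30
  groups <- rep(c("small", sprintf("big%d", 1:4)), c(6, rep(6, 4)))
  set.seed(81)
  m <- matrix(rpois(40 * n, 50), 40, n,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:n)))
  m["g01", ] <- 0
  m["g01", groups == "small"] <- 500   # well above 1 CPM in its group only
  ee <- expression_experiment(
    m, data.frame(gene_id = rownames(m)),
    data.frame(sample_id = colnames(m), donor_id = "d", sex = "unknown",
               major_site = "m", sub_site = groups, merged_group = groups))
  aware <- filter_low_genes(ee, group_column = "merged_group")   # threshold 3
  agn <- filter_low_genes(ee, group_column = NULL)               # threshold 15
  expect_true("g01" %in% aware$result$retained_ids)
  expect_false("g01" %in% agn$result$retained_ids)
})

test_that("chromosome and missing-gene filters remove exactly the targeted genes", {
  ee <- make_toy_experiment()  # X: g3; Y: g5, g9; MT: g7; all-zero: g2

  f <- filter_genes_by_chromosome(ee, c("X", "Y", "MT"), mode = "remove")
  expect_setequal(f$result$removed_ids, c("g3", "g5", "g7", "g9"))
  expect_identical(nrow(f$experiment$counts), 6L)

  k <- filter_genes_by_chromosome(ee, "Y", mode = "keep")
  expect_setequal(k$result$retained_ids, c("g5", "g9"))

  mt <- filter_genes_by_chromosome(ee, "M", mode = "keep")  # alias for MT
  expect_setequal(mt$result$retained_ids, "g7")

  none <- filter_genes_by_chromosome(ee, character(0), mode = "remove")
  expect_identical(none$experiment$counts, ee$counts)

  fm <- filter_missing_genes(ee)
  expect_identical(fm$result$removed_ids, "g2")
  expect_true("g7" %in% fm$result$retained_ids)  # single count of 1 retained
  again <- filter_missing_genes(fm$experiment)
  expect_length(again$result$removed_ids, 0)
})

test_that("biotype tallies match a brute-force count and fractions sum to one", {
  ee <- make_toy_experiment()
  bs <- biotype_summary(ee)
  expect_equal(sum(bs$fraction), 1, tolerance = 1e-9)
  expect_identical(bs$count[bs$biotype == "protein_coding"], 6L)
  expect_equal(bs$fraction[bs$biotype == "pseudogene"], 0.2)

  tab <- table(ee$gene_table$biotype)
  for (b in names(tab)) {
    expect_identical(bs$count[bs$biotype == b], as.integer(tab[[b]]))
  }
})
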