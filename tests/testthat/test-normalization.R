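test_that("quantile normalization reproduces the mean-order-statistic reference", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 6, 8))
  r <- quantile_normalize(m)
  expect_equal(unname(r$normalized),
               cbind(c(2.5, 4, 5.5), c(2.5, 4, 5.5)))
  expect_equal(r$global_reference$values, c(2.5, 4, 5.5))

  ident <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
  expect_equal(quantile_normalize(ident)$normalized, ident)  # fixed point

  expect_warning(one <- quantile_normalize(matrix(1:3, 3, 1)), "single sample")
  expect_equal(unname(one$normalized), matrix(1:3, 3, 1), ignore_attr = TRUE)
})

test_that("ties receive the mean of the tied reference values", {
  # sample b has a two-way tie at its two lowest ranks
  m <- cbind(a = c(1, 2, 3, 4), b = c(5, 5, 7, 9))
  r <- quantile_normalize(m)
  ref <- rowMeans(cbind(sort(m[, "a"]), sort(m[, "b"])))
  expect_equal(unname(r$normalized[, "b"]),
               c(mean(ref[1:2]), mean(ref[1:2]), ref[3], ref[4]))
  # the tie absorbs the mean of the two reference slots it spans
  expect_equal(sum(r$normalized[, "b"]), sum(ref))
})

test_that("quantile normalization agrees with limma's on tie-free data", {
  # on tie-free matrices both map rank k to the k-th mean order statistic;
  # tie handling intentionally differs (mean of tied references here vs
  # limma's rank interpolation), so the cross-check uses continuous data
  set.seed(91)
  m <- matrix(rlnorm(200 * 6, 3, 1), 200, 6)
  ours <- quantile_normalize(m)$normalized
  theirs <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
  # tie-free samples end up with identical sorted vectors
  mt <- matrix(rnorm(100 * 4), 100, 4)
  q <- quantile_normalize(mt)$normalized
  for (j in 2:4) expect_equal(sort(q[, j]), sort(q[, 1]), tolerance = 1e-10)
})

test_that("qsmooth matches a literal transcription of its definition (window 1)", {
  # 4 genes x 4 samples, 2 groups with a planted shift
  m <- cbind(a1 = c(2, 4, 6, 8), a2 = c(1, 5, 7, 9),
             b1 = c(12, 14, 16, 30), b2 = c(11, 13, 19, 28))
  groups <- c("a", "a", "b", "b")
  r <- qsmooth_normalize(m, groups, window_fraction = 0)
  expect_equal(unname(r$normalized), unname(brute_qsmooth(m, groups)),
               tolerance = 1e-12)
  expect_true(all(r$weights >= 0 & r$weights <= 1))

  set.seed(101)
  for (i in 1:5) {
    m <- matrix(rnbinom(60 * 6, mu = 40, size = 1), 60, 6)
    groups <- rep(c("g1", "g2", "g3"), each = 2)
    r <- qsmooth_normalize(m, groups, window_fraction = 0)
    expect_equal(unname(r$normalized), unname(brute_qsmooth(m, groups)),
                 tolerance = 1e-10)
  }
})

test_that("qsmooth degenerates to global quantile normalization when groups are uninformative", {
  set.seed(111)
  m <- matrix(rnbinom(150 * 8, mu = 25, size = 1.5), 150, 8)

  # single group
  single <- qsmooth_normalize(m, rep("all", 8))
  expect_equal(single$normalized, quantile_normalize(m)$normalized,
               tolerance = 1e-12)

  # two groups with identical per-group quantile means (SSB = 0 at every k)
  m2 <- cbind(m[, 1:4], m[, 1:4])
  both <- qsmooth_normalize(m2, rep(c("u", "v"), each = 4))
  expect_equal(both$normalized, quantile_normalize(m2)$normalized,
               tolerance = 1e-12)
  expect_true(all(both$weights == 1))
})

test_that("forced weights reproduce the global and per-group normalizers", {
  set.seed(121)
  m <- matrix(rnbinom(120 * 9, mu = 2^runif(120, 0, 8), size = 1), 120, 9)
  groups <- rep(c("t1", "t2", "t3"), each = 3)
  w0 <- qsmooth_normalize(m, groups, weights = rep(0, nrow(m)))
  expect_equal(w0$normalized, quantile_normalize_per_group(m, groups)$normalized,
               tolerance = 1e-12)
  w1 <- qsmooth_normalize(m, groups, weights = rep(1, nrow(m)))
  expect_equal(w1$normalized, quantile_normalize(m)$normalized,
               tolerance = 1e-12)
})

test_that("qsmooth preserves within-sample rank order and sample shape", {
  set.seed(131)
  m <- matrix(rnbinom(200 * 6, mu = 30, size = 0.8), 200, 6)
  groups <- rep(c("a", "b"), each = 3)
  r <- qsmooth_normalize(m, groups)
  expect_identical(dim(r$normalized), dim(m))
  for (j in 1:6) {
    o <- order(m[, j])
    expect_true(all(diff(r$normalized[o, j]) >= -1e-12))
  }
  # permutation equivariance in samples
  p <- sample(6)
  rp <- qsmooth_normalize(m[, p], groups[p])
  expect_equal(rp$normalized, r$normalized[, p], tolerance = 1e-12)
})

test_that("per-group quantile normalization is blockwise and warns on singletons", {
  set.seed(141)
  m <- matrix(rnbinom(80 * 7, mu = 20, size = 1), 80, 7,
              dimnames = list(NULL, paste0("s", 1:7)))
  groups <- c("a", "a", "a", "b", "b", "b", "c")
  expect_warning(r <- quantile_normalize_per_group(m, groups), "single sample")
  expect_equal(r$normalized[, 1:3],
               quantile_normalize(m[, 1:3])$normalized, tolerance = 1e-12)
  expect_equal(r$normalized[, 4:6],
               quantile_normalize(m[, 4:6])$normalized, tolerance = 1e-12)
  expect_equal(r$normalized[, 7], m[, 7])  # singleton untouched

  onegrp <- quantile_normalize_per_group(m, rep("x", 7))
  expect_equal(onegrp$normalized, quantile_normalize(m)$normalized,
               tolerance = 1e-12)
})

test_that("normalize_tissue_aware stores a 'normalized' assay recomputed from raw counts", {
  sim <- simulate_experiment(n_groups = 2, samples_per_group = 5,
                             n_genes = 120, seed = 6)
  ee <- normalize_tissue_aware(sim$experiment, method = "qsmooth")
  expect_true("normalized" %in% names(ee$assays))
  expect_identical(ee$counts, sim$experiment$counts)  # raw preserved

  again <- normalize_tissue_aware(ee, method = "qsmooth")
  expect_equal(assay(again), assay(ee))               # idempotent on raw

  pg <- normalize_tissue_aware(sim$experiment, method = "quantile_per_group")
  expect_false(isTRUE(all.equal(assay(pg), assay(ee))))  # methods differ

  single <- sim$experiment
  single$sample_table$merged_group <- "one"
  sq <- normalize_tissue_aware(single, method = "qsmooth")
  expect_equal(assay(sq), quantile_normalize(single$counts)$normalized,
               tolerance = 1e-12)

  unpop <- sim$experiment
  unpop$sample_table$merged_group <- NA_character_
  expect_error(normalize_tissue_aware(unpop), "not populated")
})

test_that("group references fit their samples better than the global reference", {
  worse <- 0
  for (s in 1:10) {
    sim <- simulate_experiment(n_groups = 3, samples_per_group = 6,
                               n_genes = 150, tissue_specific_fraction = 0.3,
                               group_shift_log2 = 3, seed = 200 + s)
    g <- sim$experiment$sample_table$merged_group
    m <- sim$experiment$counts
    r_glob <- reference_rmse(m, reference_scope = "global")
    r_grp <- reference_rmse(m, g, reference_scope = "group")
    if (mean(r_grp) >= mean(r_glob)) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("reference RMSE is zero for samples identical to their reference", {
  m <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(unname(reference_rmse(m, reference_scope = "global")), c(0, 0))
  g <- c("x", "x")
  expect_equal(unname(reference_rmse(m, g, reference_scope = "group")), c(0, 0))
})
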