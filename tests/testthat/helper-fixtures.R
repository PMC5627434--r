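# Small deterministic fixtures shared across test files.

# 10 genes x 6 samples, two 3-sample sub-sites, genes spread over
# autosomes/X/Y/MT with mixed biotypes.
make_toy_experiment <- function() {
  counts <- matrix(
    c(10,  12,   9,  30,  28,  33,
      0,    0,   0,   0,   0,   0,   # all-zero gene
      100, 90, 110,   2,   1,   3,
      5,    6,   4,   5,   6,   4,
      1,    0,   2,   0,   1,   0,
      50,  55,  48,  52,  49,  51,
      0,    0,   1,   0,   0,   0,
      8,    7,   9, 200, 180, 210,
      20,  22,  18,  21,  19,  23,
      3,    2,   4,  80,  90,  70),
    nrow = 10, byrow = TRUE,
    dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  gene_table <- data.frame(
    gene_id = paste0("g", 1:10),
    chromosome = c("1", "2", "X", "3", "Y", "4", "MT", "5", "Y", "6"),
    biotype = c("protein_coding", "pseudogene", "protein_coding",
                "protein_coding", "lincRNA", "protein_coding", "pseudogene",
                "protein_coding", "protein_coding", "lincRNA"),
    stringsAsFactors = FALSE)
  sample_table <- data.frame(
    sample_id = paste0("s", 1:6),
    donor_id = paste0("d", 1:6),
    sex = rep(c("male", "female"), 3),
    major_site = "site",
    sub_site = rep(c("siteA", "siteB"), each = 3),
    merged_group = rep(c("A", "B"), each = 3),
    stringsAsFactors = FALSE)
  expression_experiment(counts, gene_table, sample_table)
}

# Literal per-entry CPM recomputation (independent of cpm()).
brute_cpm <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) {
    lib <- sum(m[, j])
    for (i in seq_len(nrow(m))) out[i, j] <- m[i, j] / lib * 1e6
  }
  out
}

# Literal per-gene low-expression filter (independent of filter_low_genes()).
brute_low_filter <- function(m, cpm_threshold, min_samples) {
  cm <- brute_cpm(m)
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    npass <- 0
    for (j in seq_len(ncol(m))) if (cm[i, j] >= cpm_threshold) npass <- npass + 1
    keep[i] <- npass >= min_samples
  }
  keep
}

# Literal transcription of the smooth quantile normalization post-condition
# with explicit loops and no smoothing (window 1); the independent oracle
# for qsmooth_normalize.
brute_qsmooth <- function(m, groups) {
  ng <- nrow(m); ns <- ncol(m)
  Q <- matrix(0, ng, ns)
  for (j in seq_len(ns)) Q[, j] <- sort(m[, j])
  qbar <- rowMeans(Q)
  lv <- unique(groups)
  qbar_g <- sapply(lv, function(g) rowMeans(Q[, groups == g, drop = FALSE]))
  out <- m
  for (k in seq_len(ng)) {
    sst <- sum((Q[k, ] - qbar[k])^2)
    ssb <- 0
    for (g in seq_along(lv)) {
      n_g <- sum(groups == lv[g])
      ssb <- ssb + n_g * (qbar_g[k, g] - qbar[k])^2
    }
    w <- if (sst == 0) 1 else 1 - ssb / sst
    w <- min(1, max(0, w))
    for (j in seq_len(ns)) {
      g <- match(groups[j], lv)
      Q[k, j] <- w * qbar[k] + (1 - w) * qbar_g[k, g]
    }
  }
  for (j in seq_len(ns)) {
    x <- m[, j]
    target <- Q[, j]
    y <- numeric(ng)
    y[order(x)] <- target
    for (v in unique(x)) {
      idx <- which(x == v)
      y[idx] <- mean(y[idx])
    }
    out[, j] <- y
  }
  out
}
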