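---
title: "Tissue-aware preprocessing and smooth quantile normalization"
author: "tanorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-aware preprocessing and smooth quantile normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tanorm)
```

## The problem

Bulk RNA-seq cohorts that span many tissues (or other strongly distinct
phenotype groups) violate the assumptions behind the standard preprocessing
toolkit. Most normalization methods assume that all samples express nearly
the same genes with nearly the same distribution; across tissues that is
false — each tissue expresses a mixture of shared and tissue-specific genes,
and pooled count distributions grow a spike at zero as more tissues enter
the cohort. Gene filters tuned to homogeneous studies discard exactly the
tissue-specific genes that make cross-tissue comparison interesting. And at
cohort scale, annotation errors (samples recorded with the wrong sex, or
sub-sites that are transcriptionally indistinguishable treated as distinct
groups) are frequent enough that they must be screened for, not assumed
away.

`tanorm` chains the four stages such a cohort needs, in order:

1. **sample QC** — flag samples whose recorded sex contradicts their
   Y-chromosome expression;
2. **merge assessment** — decide, per body site, whether its sampled
   sub-sites are transcriptionally distinguishable or should be pooled into
   one group;
3. **tissue-aware gene filtering** — remove genes too weakly expressed to
   normalize, with a threshold scaled to the *smallest* group so
   group-specific genes survive;
4. **group-aware normalization** — smooth quantile normalization, which
   assumes distributional similarity only *within* groups.

Every stage consumes and returns one container, the
`ExpressionExperiment` (counts + gene table + sample table + assays +
provenance log), so stages can be run individually or through
`run_pipeline()` / the bundled command-line wrapper.

## Ordination-based QC

Both QC stages embed samples by principal coordinate analysis (classical
multidimensional scaling): Gower double-centering of \(-d^2/2\) followed by
eigendecomposition, with coordinates scaled so that pairwise Euclidean input
distances are reproduced exactly when all axes are kept. PCoA is preferred
over correlation-based PCA here because distances between samples are
directly interpretable and large average shifts in expression are not
hidden by correlation. Distances are computed on \(\log_2(x + c)\) counts.

The pseudo-count \(c\) defaults to 1 (`transform_offset = 1`), which maps
zero counts to zero and is well behaved in distance computations;
\(c = 0.5\) (the classical continuity correction) is equally defensible and
both presets are exposed everywhere the transform is used.

Two numerical conventions make ordinations reproducible across
eigen-solvers: each axis's sign is canonicalized (largest-magnitude
coordinate positive), and negative eigenvalues — impossible for Euclidean
input, possible for general dissimilarities — contribute no coordinates and
are excluded from the variance-explained denominator, with a warning.
`n_axes_for_90pct` reports how many axes reach 90% of the variance, the
depth to which ordination plots should be inspected by eye.

**Sex screen** (`check_misannotation`): the historical practice is visual —
plot the first two coordinates of a Y-chromosome-only ordination and see
which samples sit in the wrong cloud. To automate it, this package adds an
explicit decision rule: 2-means clustering (10 restarts under a fixed
internal seed) on the first coordinate, each cluster labeled by the
majority recorded sex of its members, and any sample disagreeing with its
cluster's majority flagged. One axis suffices for a binary contrast whose
separation dominates the first coordinate; the full ordination is returned
so the call can always be reviewed visually. Samples with unknown sex are
clustered but never flagged (there is no annotation to contradict). A
degenerate geometry — all samples essentially coincident on the marker
genes — yields a warning and no flags rather than an arbitrary partition.

**Merge assessment** (`assess_merge`): restricted to one major site, X/Y/MT
genes excluded (sex and mitochondrial signal would confound the tissue
contrast), the 1000 most variable genes ranked by the unbiased variance of
log2 counts (1000 is convention; results are insensitive to the exact
number, and ranking on the log scale keeps a handful of huge-count genes
from monopolizing the ranking). The separation of sub-site labels in the
first-two-axes plane is scored by mean silhouette width. The thresholds —
recommend *merge* below 0.25, *keep separate* above 0.5, *inspect*
between — operationalize what was historically a visual call; 0.5 is the
usual "reasonable structure" silhouette landmark and 0.25 the usual "no
substantial structure" one. Both are parameters, and the recommendation is
deliberately three-valued so that borderline sites are sent to a human, as
they would have been anyway.

## Tissue-aware filtering

A gene is kept iff its CPM (count divided by library size, times \(10^6\))
reaches `cpm_threshold` (default 1) in at least `min_samples` samples.
The two modes differ only in the threshold:

* **tissue-aware**: `min_samples` = half the size of the smallest phenotype
  group. With the bundled 38-group tissue table (smallest group: kidney
  cortex, 36 samples) this is 18 — a gene expressed consistently in even
  the smallest tissue survives.
* **tissue-agnostic**: `min_samples` = half of all samples, which removes
  any gene expressed only in groups that together hold less than half the
  cohort — precisely the tissue-specific genes.

Three boundary conventions are fixed and tested rather than left implicit:
pass counts are pooled over **all** samples (the smallest group sets the
threshold only); the CPM comparison is `>=` (a gene must *reach* the
threshold); and `min_samples` is kept as an exact, possibly fractional real
(n/2, no rounding) compared with `>=` — identical to rounding up for even
group sizes, and unambiguous for odd ones. Library sizes are recomputed on
the matrix as passed in, after any upstream filters, and this is recorded
in provenance. Whether pass counts should instead be accumulated per group
is a genuinely open reading of the tissue-aware rule; the pooled reading is
implemented because it makes "18 of 36" arithmetic exact.

## Smooth quantile normalization

Full quantile normalization replaces each sample's k-th order statistic by
the cross-sample mean of k-th order statistics. Across tissues that
reference represents nobody: it is dominated by the largest tissue and by
every other tissue's zero spike. Smooth quantile normalization keeps the
global reference only where the data support it. With \(Q(k,j)\) the k-th
order statistic of sample \(j\), \(\bar q_k\) the global and
\(\bar q_{g,k}\) the group mean references:

\[
SST_k = \sum_j (Q(k,j) - \bar q_k)^2,\qquad
SSB_k = \sum_g n_g (\bar q_{g,k} - \bar q_k)^2,
\]

\[
\hat w_k = 1 - SSB_k / SST_k \quad (\hat w_k = 1 \text{ when } SST_k = 0),
\]

smoothed by a running median over a window of `window_fraction` (default
5%) of the quantile indices (forced odd) and clamped to \([0,1]\). Sample
\(j\) in group \(g\) receives \(w_k \bar q_k + (1-w_k)\bar q_{g,k}\) at
rank \(k\). Where groups agree the weight is near 1 and normalization is
global; where between-group variation dominates a quantile — the zero spike
of tissue-specific genes — the weight drops and each group keeps its own
reference. Setting all weights to 1 recovers global quantile normalization
exactly; all 0 recovers per-group quantile normalization; a single group
makes the two references coincide. All three identities are tested, and a
`weights` argument exposes the forced-weight limits directly.

Ties are resolved identically in all three normalizers: the tied entries of
a sample receive the *mean of the reference values at the tied ranks*.
Count data is tie-heavy at zero, so an unstated tie rule would make outputs
irreproducible; note this is a genuine convention choice — rank-interpolation
schemes used elsewhere give slightly different values in the tied block.
Zeros are included in all quantile computations (never trimmed): the zero
spike is exactly what the group references must absorb. Normalized output
is continuous and never re-rounded; raw counts are preserved unchanged and
the `"normalized"` assay is always recomputed from them, so normalization
is idempotent.

The **RMSE diagnostic** (`reference_rmse`) quantifies why the grouping
matters: per sample, the root-mean-square difference between its log2
quantiles and a reference's log2 quantiles, with the reference the global
or the group mean-quantile vector computed on *raw* quantiles — the
diagnostic motivates the choice of normalization, so it must precede it.
On heterogeneous cohorts the group-scope RMSE is systematically far below
the global-scope RMSE.

## The synthetic test bed

The simulator (`simulate_experiment`, `simulate_mergeable_subsites`)
generates the structure each stage's claims are tested against, with the
ground truth returned alongside:

* counts are negative binomial with variance \(\mu + \phi\mu^2\)
  (\(\phi = 0.5\) by default, a typical bulk RNA-seq dispersion), baseline
  means log-normal (median 50, \(\sigma_{\log} = 1.2\)), and per-sample
  library-size factors uniform on \([0.7, 1.3]\);
* each group owns a disjoint tissue-specific gene set, up-shifted
  \(2^2\)-fold inside the group and set to a near-zero mean of 0.05
  outside it — near-zero rather than structural zero so the CPM boundary
  is actually exercised, while still giving the > 80% zero fraction that
  makes pooled distributions spike at zero;
* Y-chromosome genes are expressed in genetically male profiles only
  (default contrast \(2^{10}\) over a 0.05 female floor; the sex-screen
  recovery tests use the much harder boundary condition of a \(2^4\)
  contrast over a floor of 2, i.e. the weakest effect the screen is
  claimed to handle);
* misannotation flips the *recorded* sex of a chosen fraction of samples
  and leaves their expression untouched;
* one global seed fixes the design and each sample is drawn from its own
  seed-derived substream, so output is bit-reproducible and independent of
  generation order.

What the simulator does **not** emulate: batch and center effects,
gene-length and GC bias, correlated genes, donor effects across tissues, or
any real cohort's empirical per-tissue distributions. Passing tests
therefore demonstrate that each method recovers the structure it targets
under its own model assumptions — not that those assumptions hold in any
particular study.

Test problem sizes were chosen so the full suite exercises every recovery
claim at meaningful replication (50 seeds for the sex screen, 20 for merge
calls and the RMSE direction, 100 random matrices against the brute-force
filter oracle) while running in seconds: simulations of 100–500 genes and
16–40 samples, where every effect the tests assert is comfortably
detectable.

## Degenerate inputs and numerical conventions

* All-identical samples: the sex screen warns and flags nothing; PCoA
  returns a single zero axis.
* Singleton normalization groups are returned unchanged with a warning;
  a single sample is a quantile-normalization fixed point.
* `min_samples` larger than the cohort warns (everything may be removed)
  rather than erroring — an empty retained set is a legitimate outcome.
* Variance ranking ties break by input gene order; gene and sample order
  is significant and never silently re-sorted, so quantile mappings under
  ties are reproducible.
* Chromosome `"M"` is accepted as an alias of `"MT"`; missing chromosome
  or biotype annotations become `"unknown"` and are never dropped.

## Known limitations

* The merge and sex-screen decision rules are deliberately simple
  (first-axis 2-means; first-two-axes silhouette). Sites with more than two
  genuinely distinct sub-clusters need iterative re-assessment on subsets,
  which the API supports but does not automate — the stopping rule is the
  analyst's.
* Smoothing weights are defined per quantile index; with very few genes the
  running-median window collapses to 1 and the weights are unsmoothed.
* The bundled 38-group tissue table ships as a reference fixture for the
  merge map and threshold arithmetic; the package makes no claim of
  reproducing any specific cohort's full processed expression values, which
  would require that cohort's data.
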