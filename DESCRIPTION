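Package: tanorm
Title: Tissue-Aware Preprocessing and Smooth Quantile Normalization for
    Heterogeneous RNA-Seq Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preprocessing pipeline for large multi-tissue RNA-Seq count
    studies: sample-annotation quality control by principal coordinate
    analysis on chromosome-restricted expression (sex-misannotation
    screening), assessment of whether related sample subgroups should be
    merged, tissue-aware low-expression gene filtering based on a
    counts-per-million threshold scaled to the smallest phenotype group,
    and group-aware (smooth) quantile normalization with
    reference-divergence diagnostics. Includes a negative-binomial
    multi-group count simulator with known ground truth for validating
    every stage, tabular/sparse matrix input and output, and a
    command-line interface chaining the stages.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    cluster,
    grDevices,
    graphics,
    jsonlite,
    Matrix,
    optparse,
    stats,
    utils
Suggests:
    edgeR,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
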