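#' Annotated expression experiment
#'
#' The container every pipeline stage consumes and returns: a gene-by-sample
#' count matrix together with per-gene and per-sample annotation tables, any
#' number of additional gene-by-sample assays (e.g. `"normalized"`), and an
#' ordered provenance log recording each operation applied.
#'
#' Counts are stored as doubles even when the input is integral so that raw
#' counts and continuous assays share one matrix contract; [validate_experiment()]
#' checks integrality of the raw counts only when `raw = TRUE`.
#'
#' @param counts numeric gene-by-sample matrix of non-negative read counts.
#'   Row and column names, when absent, are taken from the annotation tables.
#' @param gene_table data frame with one row per gene; must contain
#'   `gene_id`, and is completed with `chromosome`, `biotype` and `symbol`
#'   columns (missing values become `"unknown"` / `NA`).
#' @param sample_table data frame with one row per sample; must contain
#'   `sample_id`, `donor_id`, `sex`, `major_site`, `sub_site`. A
#'   `merged_group` column is added (all `NA`) when absent.
#' @param assays named list of additional gene-by-sample matrices sharing the
#'   shape and dimnames of `counts`.
#' @param provenance list of prior operation records (normally empty; filled
#'   by the pipeline stages).
#'
#' @return An object of class `ExpressionExperiment`: a list with elements
#'   `counts`, `gene_table`, `sample_table`, `assays`, `provenance`.
#' @seealso [validate_experiment()], [subset_experiment()], [read_experiment()]
#' @examples
#' ee <- expression_experiment(
#'   counts = matrix(rpois(12, 10), 4, 3,
#'                   dimnames = list(paste0("g", 1:4), paste0("s", 1:3))),
#'   gene_table = data.frame(gene_id = paste0("g", 1:4)),
#'   sample_table = data.frame(sample_id = paste0("s", 1:3),
#'                             donor_id = paste0("d", 1:3), sex = "female",
#'                             major_site = "skin", sub_site = "skin_leg")
#' )
#' validate_experiment(ee)
#' @export
expression_experiment <- function(counts, gene_table, sample_table,
                                  assays = list(), provenance = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  gene_table <- as.data.frame(gene_table, stringsAsFactors = FALSE)
  sample_table <- as.data.frame(sample_table, stringsAsFactors = FALSE)
  if (is.null(gene_table$gene_id)) stop("gene_table must have a 'gene_id' column")
  if (is.null(sample_table$sample_id)) stop("sample_table must have a 'sample_id' column")

  for (col in c("donor_id", "sex", "major_site", "sub_site")) {
    if (is.null(sample_table[[col]])) {
      stop("sample_table must have a '", col, "' column")
    }
  }
  if (is.null(sample_table$merged_group)) {
    sample_table$merged_group <- NA_character_
  }
  if (is.null(gene_table$chromosome)) gene_table$chromosome <- "unknown"
  if (is.null(gene_table$biotype)) gene_table$biotype <- "unknown"
  if (is.null(gene_table$symbol)) gene_table$symbol <- NA_character_
  gene_table$chromosome <- normalize_chromosome(gene_table$chromosome)
  gene_table$biotype[is.na(gene_table$biotype) | gene_table$biotype == ""] <- "unknown"
  sample_table$sex <- as.character(sample_table$sex)
  sample_table$sex[is.na(sample_table$sex) | sample_table$sex == ""] <- "unknown"

  rownames(counts) <- as.character(gene_table$gene_id)
  colnames(counts) <- as.character(sample_table$sample_id)
  rownames(gene_table) <- NULL
  rownames(sample_table) <- NULL
  assays <- lapply(assays, function(a) {
    a <- as.matrix(a)
    storage.mode(a) <- "double"
    dimnames(a) <- dimnames(counts)
    a
  })

  structure(
    list(counts = counts, gene_table = gene_table,
         sample_table = sample_table, assays = assays,
         provenance = provenance),
    class = "ExpressionExperiment"
  )
}

#' @export
dim.ExpressionExperiment <- function(x) dim(x$counts)

#' @export
dimnames.ExpressionExperiment <- function(x) dimnames(x$counts)

#' Extract the raw count matrix
#' @param x an `ExpressionExperiment`.
#' @return numeric gene-by-sample matrix.
#' @export
counts <- function(x) {
  stopifnot(inherits(x, "ExpressionExperiment"))
  x$counts
}

#' Extract a named assay matrix
#' @param x an `ExpressionExperiment`.
#' @param name assay name, e.g. `"normalized"`.
#' @return numeric gene-by-sample matrix.
#' @export
assay <- function(x, name = "normalized") {
  stopifnot(inherits(x, "ExpressionExperiment"))
  if (is.null(x$assays[[name]])) {
    stop("no assay named '", name, "'; available: ",
         paste(names(x$assays), collapse = ", "))
  }
  x$assays[[name]]
}

#' @export
print.ExpressionExperiment <- function(x, ...) {
  cat(sprintf("ExpressionExperiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  grp <- x$sample_table$merged_group
  if (any(!is.na(grp))) {
    cat(sprintf("  merged groups: %d\n", length(unique(grp[!is.na(grp)]))))
  }
  if (length(x$assays)) {
    cat("  assays:", paste(names(x$assays), collapse = ", "), "\n")
  }
  cat(sprintf("  provenance: %d operation(s) recorded\n", length(x$provenance)))
  invisible(x)
}

# Append one operation record to the provenance log.
log_provenance <- function(expr, name, params = list()) {
  expr$provenance <- c(expr$provenance, list(list(
    name = name, params = params, timestamp = format(Sys.time(), usetz = TRUE)
  )))
  expr
}

#' Check an experiment against the container invariants
#'
#' Reports, rather than raises: every violated invariant yields one
#' human-readable string naming the offending gene/sample/assay. An empty
#' character vector means the experiment is well formed.
#'
#' Checked: annotation tables match the matrix dimensions; gene and sample
#' identifiers are unique and non-empty; all counts are finite and
#' non-negative (and integral when `raw = TRUE`); every assay matrix has the
#' shape and dimnames of the count matrix; `merged_group`, when set, is
#' non-empty.
#'
#' @param expr an `ExpressionExperiment`.
#' @param raw if `TRUE`, additionally require the count matrix to be integral.
#' @return character vector of violation descriptions (empty when valid).
#' @export
validate_experiment <- function(expr, raw = FALSE) {
  v <- character(0)
  if (!inherits(expr, "ExpressionExperiment")) {
    return("object is not an ExpressionExperiment")
  }
  cm <- expr$counts
  gt <- expr$gene_table
  st <- expr$sample_table
  if (nrow(gt) != nrow(cm)) {
    v <- c(v, sprintf("gene_table has %d rows but counts has %d", nrow(gt), nrow(cm)))
  }
  if (nrow(st) != ncol(cm)) {
    v <- c(v, sprintf("sample_table has %d rows but counts has %d columns",
                      nrow(st), ncol(cm)))
  }
  gid <- as.character(gt$gene_id)
  sid <- as.character(st$sample_id)
  if (any(is.na(gid) | gid == "")) v <- c(v, "empty gene_id")
  if (any(is.na(sid) | sid == "")) v <- c(v, "empty sample_id")
  dup <- unique(gid[duplicated(gid)])
  if (length(dup)) {
    v <- c(v, sprintf("duplicated gene_id: %s", paste(dup, collapse = ", ")))
  }
  dup <- unique(sid[duplicated(sid)])
  if (length(dup)) {
    v <- c(v, sprintf("duplicated sample_id: %s", paste(dup, collapse = ", ")))
  }
  bad <- which(!is.finite(cm), arr.ind = TRUE)
  if (nrow(bad)) {
    v <- c(v, sprintf("non-finite count at gene %s, sample %s",
                      rownames(cm)[bad[, 1]], colnames(cm)[bad[, 2]]))
  }
  neg <- which(is.finite(cm) & cm < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    v <- c(v, sprintf("negative count at gene %s, sample %s",
                      rownames(cm)[neg[, 1]], colnames(cm)[neg[, 2]]))
  }
  if (raw) {
    nonint <- which(is.finite(cm) & cm != round(cm), arr.ind = TRUE)
    if (nrow(nonint)) {
      v <- c(v, sprintf("non-integer raw count at gene %s, sample %s",
                        rownames(cm)[nonint[, 1]], colnames(cm)[nonint[, 2]]))
    }
  }
  for (nm in names(expr$assays)) {
    a <- expr$assays[[nm]]
    if (!identical(dim(a), dim(cm))) {
      v <- c(v, sprintf("assay '%s' has shape %dx%d, expected %dx%d",
                        nm, nrow(a), ncol(a), nrow(cm), ncol(cm)))
    } else if (!identical(dimnames(a), dimnames(cm))) {
      v <- c(v, sprintf("assay '%s' row/column identities differ from counts", nm))
    }
  }
  mg <- st$merged_group
  if (!is.null(mg) && any(!is.na(mg) & mg == "")) {
    v <- c(v, sprintf("empty merged_group for sample %s",
                      sid[!is.na(mg) & mg == ""]))
  }
  v
}

#' Subset an experiment by gene and/or sample identifiers
#'
#' Returns an experiment containing exactly the requested genes and samples,
#' in the requested order; annotation tables and every assay are subset
#' consistently and the operation is appended to the provenance log.
#'
#' @param expr an `ExpressionExperiment`.
#' @param gene_ids character vector of gene ids to keep (default: all, in
#'   current order).
#' @param sample_ids character vector of sample ids to keep (default: all).
#' @return the subset `ExpressionExperiment`.
#' @export
subset_experiment <- function(expr, gene_ids = NULL, sample_ids = NULL) {
  stopifnot(inherits(expr, "ExpressionExperiment"))
  gid <- rownames(expr$counts)
  sid <- colnames(expr$counts)
  gene_ids <- gene_ids %||% gid
  sample_ids <- sample_ids %||% sid
  gi <- match(gene_ids, gid)
  si <- match(sample_ids, sid)
  if (anyNA(gi)) stop("unknown gene id(s): ",
                      paste(gene_ids[is.na(gi)], collapse = ", "))
  if (anyNA(si)) stop("unknown sample id(s): ",
                      paste(sample_ids[is.na(si)], collapse = ", "))
  out <- expr
  out$counts <- expr$counts[gi, si, drop = FALSE]
  out$gene_table <- expr$gene_table[gi, , drop = FALSE]
  rownames(out$gene_table) <- NULL
  out$sample_table <- expr$sample_table[si, , drop = FALSE]
  rownames(out$sample_table) <- NULL
  out$assays <- lapply(expr$assays, function(a) a[gi, si, drop = FALSE])
  log_provenance(out, "subset",
                 list(n_genes = length(gi), n_samples = length(si)))
}

#' @export
`[.ExpressionExperiment` <- function(x, i, j, ...) {
  gid <- rownames(x$counts)
  sid <- colnames(x$counts)
  gsel <- if (missing(i)) gid else if (is.character(i)) i else gid[i]
  ssel <- if (missing(j)) sid else if (is.character(j)) j else sid[j]
  subset_experiment(x, gsel, ssel)
}
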