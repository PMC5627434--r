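#' Read an expression experiment from disk
#'
#' Reads a gene-by-sample count matrix plus its sample and gene annotation
#' tables and returns a validated [expression_experiment()]. Two count-matrix
#' dialects are supported:
#'
#' * `"tsv"` — dense tab-separated table, gene id in the first column, header
#'   row of sample ids;
#' * `"mtx"` — MatrixMarket coordinate format, with newline-delimited row and
#'   column id sidecar files at `<counts_path>.rows` / `<counts_path>.cols`.
#'
#' Count columns are reordered to the sample-table order when the file stores
#' them permuted (the reordering is recorded in the provenance log). Sample or
#' gene id sets that do not match the annotation tables raise an error listing
#' up to the first 10 offenders on each side.
#'
#' The sample table must carry the columns `sample_id`, `donor_id`, `sex`,
#' `major_site`, `sub_site` verbatim; extra columns pass through untouched.
#' Missing gene `chromosome`/`biotype` values are read as `"unknown"`.
#'
#' @param counts_path path to the count matrix (TSV or `.mtx`).
#' @param sample_table_path path to the sample annotation TSV.
#' @param gene_table_path path to the gene annotation TSV.
#' @param format `"tsv"` or `"mtx"`.
#' @return a validated `ExpressionExperiment`.
#' @seealso [write_experiment()]
#' @export
read_experiment <- function(counts_path, sample_table_path, gene_table_path,
                            format = c("tsv", "mtx")) {
  format <- match.arg(format)
  for (p in c(counts_path, sample_table_path, gene_table_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  sample_table <- read_annotation_tsv(sample_table_path,
                                      required = c("sample_id", "donor_id", "sex",
                                                   "major_site", "sub_site"))
  gene_table <- read_annotation_tsv(gene_table_path, required = "gene_id")

  if (format == "tsv") {
    counts <- read_counts_tsv(counts_path)
  } else {
    counts <- read_counts_mtx(counts_path)
  }

  check_id_sets(rownames(counts), gene_table$gene_id, "gene", counts_path)
  check_id_sets(colnames(counts), sample_table$sample_id, "sample", counts_path)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative count(s) in ", counts_path, ", first at gene ",
         rownames(counts)[neg[1, 1]], ", sample ", colnames(counts)[neg[1, 2]])
  }

  permuted <- !identical(colnames(counts), as.character(sample_table$sample_id)) ||
    !identical(rownames(counts), as.character(gene_table$gene_id))
  counts <- counts[as.character(gene_table$gene_id),
                   as.character(sample_table$sample_id), drop = FALSE]

  ee <- expression_experiment(counts, gene_table, sample_table)
  ee <- log_provenance(ee, "read_experiment",
                       list(counts = counts_path, format = format,
                            reordered_to_annotation = permuted))
  v <- validate_experiment(ee)
  if (length(v)) stop("invalid experiment read from ", counts_path, ": ",
                      paste(v, collapse = "; "))
  ee
}

read_annotation_tsv <- function(path, required) {
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(path, " lacks required column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab
}

read_counts_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e))
  )
  if (ncol(tab) < 2L) stop(path, ": expected a gene id column plus sample columns")
  ids <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(tab[, -1L, drop = FALSE], 2, function(x) any(is.na(suppressWarnings(as.numeric(x))))))[1]
    stop(path, ": non-numeric count values in column '", names(tab)[-1L][bad],
         "' (check for a malformed line)")
  }
  rownames(m) <- ids
  m
}

read_counts_mtx <- function(path) {
  rows_path <- paste0(path, ".rows")
  cols_path <- paste0(path, ".cols")
  for (p in c(rows_path, cols_path)) {
    if (!file.exists(p)) stop("MatrixMarket sidecar not found: ", p)
  }
  m <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("failed to parse ", path, ": ",
                                         conditionMessage(e)))
  m <- as.matrix(m)
  rid <- readLines(rows_path)
  cid <- readLines(cols_path)
  if (length(rid) != nrow(m)) {
    stop(rows_path, ": ", length(rid), " ids for ", nrow(m), " matrix rows")
  }
  if (length(cid) != ncol(m)) {
    stop(cols_path, ": ", length(cid), " ids for ", ncol(m), " matrix columns")
  }
  dimnames(m) <- list(rid, cid)
  m
}

check_id_sets <- function(found, expected, what, path) {
  found <- as.character(found)
  expected <- as.character(expected)
  extra <- setdiff(found, expected)
  missing <- setdiff(expected, found)
  if (length(extra) || length(missing)) {
    trunc10 <- function(x) paste(utils::head(x, 10), collapse = ", ")
    stop(path, ": ", what, " ids disagree with the annotation table. ",
         if (length(extra)) paste0("In counts only: ", trunc10(extra), ". ") else "",
         if (length(missing)) paste0("In annotation only: ", trunc10(missing), ".") else "")
  }
}

#' Write an expression experiment to a directory
#'
#' Writes the count matrix (dense TSV or MatrixMarket with `.rows`/`.cols`
#' sidecars), the gene and sample annotation tables as TSV, the provenance
#' log as plain text, and one additional matrix file per assay (suffixed with
#' the assay name, e.g. `counts.normalized.tsv`).
#'
#' @param expr an `ExpressionExperiment`.
#' @param out_dir output directory (created if absent).
#' @param format `"tsv"` or `"mtx"`.
#' @return (invisibly) character vector of the files written.
#' @export
write_experiment <- function(expr, out_dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(expr, "ExpressionExperiment"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)

  write_matrix <- function(m, stem) {
    if (format == "tsv") {
      p <- file.path(out_dir, paste0(stem, ".tsv"))
      tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                        stringsAsFactors = FALSE)
      utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
      p
    } else {
      p <- file.path(out_dir, paste0(stem, ".mtx"))
      Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), p)
      writeLines(rownames(m), paste0(p, ".rows"))
      writeLines(colnames(m), paste0(p, ".cols"))
      p
    }
  }

  files <- c(files, write_matrix(expr$counts, "counts"))
  for (nm in names(expr$assays)) {
    files <- c(files, write_matrix(expr$assays[[nm]], paste0("counts.", nm)))
  }

  sp <- file.path(out_dir, "samples.tsv")
  utils::write.table(expr$sample_table, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gp <- file.path(out_dir, "genes.tsv")
  utils::write.table(expr$gene_table, gp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lp <- file.path(out_dir, "provenance.txt")
  writeLines(vapply(expr$provenance, function(rec) {
    sprintf("%s\t%s\t%s", rec$timestamp, rec$name, format_params(rec$params))
  }, character(1)), lp)
  invisible(c(files, sp, gp, lp))
}
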