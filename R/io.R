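# Matrix I/O: delimited text (genes in rows, header row of cell ids, first
# column of gene ids) and MatrixMarket triplets with gene/cell sidecar
# files. Orientation is never guessed; use `transpose = TRUE` when a file
# stores cells in rows.

#' Read a count matrix
#'
#' @param path File to read. For `format = "mtx"`, the MatrixMarket file;
#'   gene and cell ids are read from sidecar files.
#' @param format One of `"auto"` (by file extension), `"csv"`, `"tsv"`,
#'   `"mtx"`.
#' @param transpose Set `TRUE` if the file stores cells in rows; the matrix
#'   is transposed after reading so the result is always genes x cells.
#' @param genes,cells Sidecar files with one gene/cell id per line (MTX
#'   only). Default `genes.txt` / `cells.txt` next to `path`.
#' @return Numeric matrix, genes in rows and cells in columns, with unique
#'   dimnames; negative entries and ragged rows are rejected.
#' @export
read_counts <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        transpose = FALSE,
                        genes = file.path(dirname(path), "genes.txt"),
                        cells = file.path(dirname(path), "cells.txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    if (!file.exists(genes)) stop("gene sidecar file not found: ", genes)
    if (!file.exists(cells)) stop("cell sidecar file not found: ", cells)
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                            fill = FALSE)
    ids <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in ", path)
    rownames(m) <- ids
  }
  if (transpose) m <- t(m)
  if (anyNA(m)) stop("missing entries in ", path)
  if (any(m < 0)) stop("negative entries in ", path)
  as_count_matrix(m)
}

#' Write a count matrix
#'
#' The inverse of [read_counts()]: delimited text keeps full double
#' precision so that a write/read round trip reproduces the matrix exactly.
#'
#' @param m Numeric matrix, genes x cells, with dimnames.
#' @param path Output file.
#' @param format One of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`.
#' @param genes,cells Sidecar id files (MTX only).
#' @return Invisibly, `path`.
#' @export
write_counts <- function(m, path, format = c("auto", "csv", "tsv", "mtx"),
                         genes = file.path(dirname(path), "genes.txt"),
                         cells = file.path(dirname(path), "cells.txt")) {
  format <- match.arg(format)
  stopifnot(is.matrix(m), nrow(m) >= 1, ncol(m) >= 1)
  m <- as_count_matrix(m, require_nonneg = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot infer format from extension of ", path))
  }
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    writeLines(rownames(m), genes)
    writeLines(colnames(m), cells)
  } else {
    sep <- if (format == "csv") "," else "\t"
    dt <- data.table::data.table(gene = rownames(m), m)
    data.table::fwrite(dt, path, sep = sep)
  }
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report An `evaluation_report` (or any named list of scalars).
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("the 'jsonlite' package is required to write JSON reports")
  }
  fields <- report[vapply(report, function(v) is.numeric(v) && length(v) == 1,
                          logical(1))]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
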