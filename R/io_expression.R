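#' Read an expression matrix with its gene and cell index files
#'
#' Reads a genes-by-cells CPM matrix either from Matrix Market coordinate
#' format (`.mtx`) or from a dense CSV of bare numbers (no header, no row
#' names), together with one-entry-per-line index files for the gene and cell
#' axes. The orientation is genes in rows, cells in columns, and is validated
#' against the index file lengths.
#'
#' @param matrix_path Path to the `.mtx` or dense `.csv` matrix file.
#' @param genes_path Path to the gene index file (one symbol per line).
#' @param cells_path Path to the cell index file (one identifier per line).
#' @return An [expression_dataset()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(matrix_path, genes_path, cells_path) {
  gene_ids <- .read_index(genes_path)
  cell_ids <- .read_index(cells_path)
  first <- readLines(matrix_path, n = 1L)
  if (startsWith(first, "%%MatrixMarket") || grepl("\\.mtx$", matrix_path)) {
    m <- Matrix::readMM(matrix_path)
  } else {
    rows <- readr::read_csv(matrix_path, col_names = FALSE, comment = "#",
                            show_col_types = FALSE)
    m <- as.matrix(rows)
    dimnames(m) <- NULL
  }
  if (nrow(m) != length(gene_ids)) {
    abort(sprintf(
      "gene axis mismatch: matrix '%s' has %d rows but gene index '%s' has %d entries",
      matrix_path, nrow(m), genes_path, length(gene_ids)
    ), class = "impulscreen_format_error")
  }
  if (ncol(m) != length(cell_ids)) {
    abort(sprintf(
      "cell axis mismatch: matrix '%s' has %d columns but cell index '%s' has %d entries",
      matrix_path, ncol(m), cells_path, length(cell_ids)
    ), class = "impulscreen_format_error")
  }
  expression_dataset(m, gene_ids, cell_ids)
}

.read_index <- function(path) {
  x <- readLines(path)
  x <- x[!startsWith(x, "#") & nzchar(x)]
  x
}

#' Write an expression dataset to disk
#'
#' Writes the matrix in Matrix Market coordinate format (default) or dense CSV,
#' plus plain-text gene and cell index files. A comment line recording the
#' package version and an optional configuration hash is embedded in the matrix
#' file header so that bundles can be verified later.
#'
#' @param ds An [expression_dataset()].
#' @param matrix_path,genes_path,cells_path Output paths.
#' @param format `"mtx"` (sparse coordinate) or `"csv"` (dense).
#' @param config_hash Optional hash string stamped into the header comment.
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(ds, matrix_path, genes_path, cells_path,
                             format = c("mtx", "csv"), config_hash = NULL) {
  format <- match.arg(format)
  stamp <- .header_comment(config_hash)
  if (format == "mtx") {
    Matrix::writeMM(ds$matrix, matrix_path)
    lines <- readLines(matrix_path)
    writeLines(c(lines[1], paste0("%", stamp), lines[-1]), matrix_path)
  } else {
    con <- file(matrix_path, "w")
    writeLines(paste0("#", stamp), con)
    utils::write.table(as.matrix(ds$matrix), con, sep = ",",
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  writeLines(ds$gene_ids, genes_path)
  writeLines(ds$cell_ids, cells_path)
  invisible(matrix_path)
}

.header_comment <- function(config_hash = NULL) {
  sprintf(" impulscreen %s%s",
          as.character(utils::packageVersion("impulscreen")),
          if (is.null(config_hash)) "" else paste0(" config=", config_hash))
}
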