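#' Construct an expression dataset
#'
#' Bundles a genes-by-cells matrix of CPM (counts-per-million) values with its
#' gene and cell identifiers. The orientation is fixed: genes in rows, cells in
#' columns. Values must be non-negative and finite; identifiers must be unique.
#'
#' @param matrix A numeric matrix or a [Matrix::sparseMatrix()] with genes in
#'   rows and cells in columns. Implicit zeros of a sparse matrix are kept
#'   sparse.
#' @param gene_ids Character vector of gene symbols, one per matrix row.
#' @param cell_ids Character vector of cell identifiers, one per matrix column.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix` (a `dgCMatrix`), `gene_ids` and `cell_ids`.
#' @examples
#' m <- matrix(c(0, 5, 0, 1, 2, 0), nrow = 3)
#' ds <- expression_dataset(m, c("Grm2", "Gapdh", "Drd1"), c("c1", "c2"))
#' dim(ds$matrix)
#' @export
expression_dataset <- function(matrix, gene_ids, cell_ids) {
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (nrow(matrix) != length(gene_ids)) {
    abort(sprintf(
      "gene axis mismatch: matrix has %d rows but %d gene ids supplied",
      nrow(matrix), length(gene_ids)
    ), class = "impulscreen_format_error")
  }
  if (ncol(matrix) != length(cell_ids)) {
    abort(sprintf(
      "cell axis mismatch: matrix has %d columns but %d cell ids supplied",
      ncol(matrix), length(cell_ids)
    ), class = "impulscreen_format_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort(paste0("duplicated gene ids: ",
                 paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")),
          class = "impulscreen_validation_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort(paste0("duplicated cell ids: ",
                 paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", ")),
          class = "impulscreen_validation_error")
  }
  m <- methods::as(methods::as(Matrix::Matrix(matrix, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  bad <- which(!is.finite(m@x) | m@x < 0)
  if (length(bad)) {
    ij <- .sparse_coords(m, bad[1])
    abort(sprintf(
      "negative or non-finite CPM value at gene '%s', cell '%s'",
      gene_ids[ij[1]], cell_ids[ij[2]]
    ), class = "impulscreen_validation_error")
  }
  dimnames(m) <- list(gene_ids, cell_ids)
  structure(
    list(matrix = m, gene_ids = gene_ids, cell_ids = cell_ids),
    class = "expression_dataset"
  )
}

# row/col of the k-th stored entry of a dgCMatrix
.sparse_coords <- function(m, k) {
  j <- findInterval(k - 1L, m@p[-1L]) + 1L
  c(m@i[k] + 1L, j)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d cells, %.1f%% non-zero\n",
    nrow(x$matrix), ncol(x$matrix),
    100 * length(x$matrix@x) / prod(dim(x$matrix))
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)
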