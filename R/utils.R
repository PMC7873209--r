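#' @keywords internal
#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

# counts matrices are cells x genes (single cell) or genes x samples (bulk);
# both are stored as dgCMatrix with dimnames.
assert_counts <- function(counts, integer = FALSE) {
  if (is.matrix(counts)) counts <- as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (!methods::is(counts, "sparseMatrix")) {
    abort("`counts` must be a (sparse) matrix.")
  }
  if (!methods::is(counts, "dMatrix")) {
    counts <- as(counts, "dMatrix")  # pattern/logical sparse -> numeric
  }
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    abort("`counts` must carry row and column names (barcodes / gene ids).")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("row and column ids of `counts` must be unique.")
  }
  x <- counts@x
  if (length(x) && min(x) < 0) abort("counts must be non-negative.")
  if (integer && length(x) && any(abs(x - round(x)) > 1e-8)) {
    abort("raw counts must be integers.")
  }
  as(counts, "CsparseMatrix")
}

# Scale a non-negative vector so it sums to `total`; all-zero stays zero.
rescale_to <- function(x, total = 1) {
  s <- sum(x)
  if (s <= 0) return(x)
  x * (total / s)
}

# quantile convention used throughout: linear interpolation (type 7)
quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
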