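#' Cell-by-feature count matrix
#'
#' Validates and tags a sparse count matrix. Cells are rows, features are
#' columns; the modality records which library the counts came from (gene
#' expression, antibody-derived tags, or hashtag oligos).
#'
#' @param counts A matrix or sparse Matrix of non-negative integer counts,
#'   cells x features, with unique row (cell barcode) and column (feature id)
#'   names.
#' @param modality One of `"gene"`, `"adt"`, `"hashtag"`.
#' @return A `dgCMatrix` (cells x features) carrying a `modality` attribute.
#' @export
cell_counts <- function(counts, modality = c("gene", "adt", "hashtag")) {
  modality <- match.arg(modality)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m)
  validate_cell_counts(m)
  attr(m, "modality") <- modality
  m
}

validate_cell_counts <- function(m, what = "counts") {
  x <- m@x
  if (length(x) && (any(x < 0) || any(x != trunc(x)))) {
    abort(sprintf("%s must be non-negative integers", what),
          class = "inciteseq_format_error")
  }
  bc <- rownames(m)
  fi <- colnames(m)
  if ((is.null(bc) && nrow(m) > 0) || (is.null(fi) && ncol(m) > 0)) {
    abort("counts must carry cell barcodes (rownames) and feature ids (colnames)",
          class = "inciteseq_format_error")
  }
  if (anyDuplicated(bc)) abort("duplicate cell barcodes", class = "inciteseq_format_error")
  if (anyDuplicated(fi)) abort("duplicate feature ids", class = "inciteseq_format_error")
  invisible(m)
}

#' Modality of a count matrix
#' @param x A [cell_counts()] matrix.
#' @return `"gene"`, `"adt"` or `"hashtag"` (or `NULL` for untagged matrices).
#' @export
modality <- function(x) attr(x, "modality")
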