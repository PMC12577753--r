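#' Read a CellRanger-style count directory
#'
#' Reads a directory holding `matrix.mtx` (Matrix Market coordinate, integer,
#' 1-based; a `.gz` variant is also accepted), `features.tsv` and
#' `barcodes.tsv`. On disk features are rows (the 10x convention); the matrix
#' is transposed to cells x features in memory. Orientation is auto-detected
#' from the header dimensions against the lengths of the two annotation files.
#'
#' @param path Directory produced by [write_counts_dir()] or CellRanger.
#' @param modality Modality tag for the returned matrix.
#' @return A sparse cells x features count matrix (see [cell_counts()]).
#' @export
read_counts_dir <- function(path, modality = c("gene", "adt", "hashtag")) {
  modality <- match.arg(modality)
  mtx <- first_existing(file.path(path, c("matrix.mtx", "matrix.mtx.gz")))
  feat <- first_existing(file.path(path, c("features.tsv", "features.tsv.gz")))
  bcs <- first_existing(file.path(path, c("barcodes.tsv", "barcodes.tsv.gz")))

  features <- read_first_column(feat)
  barcodes <- read_first_column(bcs)

  m <- tryCatch(
    Matrix::readMM(mtx),
    error = function(e) abort(sprintf("malformed Matrix Market file '%s': %s",
                                      mtx, conditionMessage(e)),
                              class = "inciteseq_format_error")
  )
  if (methods::is(m, "nMatrix")) m <- methods::as(m, "dMatrix")  # pattern-only file
  if (length(m@x) && (any(m@x < 0) || any(m@x != trunc(m@x)))) {
    abort(sprintf("'%s' contains negative or non-integer entries", mtx),
          class = "inciteseq_format_error")
  }

  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                       # disk convention: features x cells
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(features)) {
    # already cells x features
  } else {
    abort(sprintf(
      "dimension mismatch in '%s': matrix is %d x %d but %d features and %d barcodes given",
      path, nrow(m), ncol(m), length(features), length(barcodes)),
      class = "inciteseq_format_error")
  }
  dimnames(m) <- list(barcodes, features)
  cell_counts(m, modality)
}

read_first_column <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) return(character())
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (!length(hit)) {
    abort(sprintf("missing file: none of %s exist", paste(paths, collapse = ", ")),
          class = "inciteseq_format_error")
  }
  hit[[1]]
}

#' Write a count matrix as a CellRanger-style directory
#'
#' Writes `matrix.mtx` (features x rows on disk, 1-based coordinate format),
#' `features.tsv` and `barcodes.tsv`. Round-trips exactly through
#' [read_counts_dir()].
#'
#' @param m A [cell_counts()] matrix (cells x features).
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_counts_dir <- function(m, path) {
  validate_cell_counts(m)
  if (any(grepl("\t", c(rownames(m), colnames(m)), fixed = TRUE))) {
    abort("barcodes/feature ids must not contain tab characters",
          class = "inciteseq_format_error")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(Matrix::t(m), file.path(path, "matrix.mtx"))
  writeLines(colnames(m) %||% character(), file.path(path, "features.tsv"))
  writeLines(rownames(m) %||% character(), file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read a flow-cytometry summary table
#'
#' Expects a TSV with columns `sample_id`, `target_id`, `percent_positive`
#' (0-100) and `mfi` (arbitrary fluorescence units), one row per
#' (sample, target) pair.
#'
#' @param path Path to the TSV file.
#' @return A tibble, validated for unique keys and in-range percentages.
#' @export
read_flow_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    target_id = readr::col_character(),
    percent_positive = readr::col_double(),
    mfi = readr::col_double()
  ), progress = FALSE)
  validate_flow_table(tbl)
}

validate_flow_table <- function(tbl) {
  need <- c("sample_id", "target_id", "percent_positive", "mfi")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    abort(sprintf("flow table missing columns: %s", paste(miss, collapse = ", ")),
          class = "inciteseq_format_error")
  }
  if (anyDuplicated(tbl[c("sample_id", "target_id")])) {
    abort("duplicate (sample_id, target_id) keys in flow table",
          class = "inciteseq_format_error")
  }
  bad <- !is.na(tbl$percent_positive) &
    (tbl$percent_positive < 0 | tbl$percent_positive > 100)
  if (any(bad)) {
    abort(sprintf("percent_positive out of [0,100] for %s",
                  paste(tbl$sample_id[bad], tbl$target_id[bad], collapse = "; ")),
          class = "inciteseq_format_error")
  }
  tibble::as_tibble(tbl)
}
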