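#' Quality-control thresholds
#'
#' Defaults follow common practice for fixed-cell experiments: at least 500
#' detected genes and 500 total counts per cell, and at most a 0.1
#' mitochondrial transcript proportion. Boundaries are inclusive: a cell
#' passes at exactly 500 genes, 500 counts or mito fraction 0.1.
#'
#' @param min_genes Minimum detected genes per cell.
#' @param min_counts Minimum total counts per cell.
#' @param max_mito_fraction Maximum mitochondrial transcript proportion.
#' @param contaminant_marker_genes Marker genes for the contaminant score
#'   (default: the B-cell markers Cd79a, Cd79b, Ms4a1).
#' @param contaminant_score_cutoff Cells whose mean `ln(1 + count)` over the
#'   marker genes exceeds this are flagged as contaminants.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 500L, min_counts = 500L,
                          max_mito_fraction = 0.1,
                          contaminant_marker_genes = c("Cd79a", "Cd79b", "Ms4a1"),
                          contaminant_score_cutoff = 2) {
  stopifnot(min_genes > 0, min_counts > 0,
            max_mito_fraction >= 0, max_mito_fraction <= 1)
  structure(list(min_genes = min_genes, min_counts = min_counts,
                 max_mito_fraction = max_mito_fraction,
                 contaminant_marker_genes = contaminant_marker_genes,
                 contaminant_score_cutoff = contaminant_score_cutoff),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' @param rna Gene-expression [cell_counts()] matrix.
#' @param mito_prefix Feature-id prefix identifying mitochondrial genes
#'   (mouse convention `"mt-"`).
#' @return A tibble: `barcode`, `total_counts`, `genes_detected`,
#'   `mito_fraction` (0 when a cell has no counts), `ln_genes` (natural log
#'   of genes detected, the standard detection-rate covariate; 0 for empty
#'   cells).
#' @export
compute_qc_metrics <- function(rna, mito_prefix = "mt-") {
  total <- Matrix::rowSums(rna)
  genes <- Matrix::rowSums(rna > 0)
  mito_idx <- startsWith(colnames(rna), mito_prefix)
  mito <- if (any(mito_idx)) Matrix::rowSums(rna[, mito_idx, drop = FALSE]) else 0
  total <- unname(as.numeric(total))
  genes <- unname(as.integer(genes))
  mito <- unname(as.numeric(mito))
  tibble::tibble(
    barcode = rownames(rna),
    total_counts = total,
    genes_detected = genes,
    mito_fraction = ifelse(total > 0, mito / total, 0),
    ln_genes = ifelse(genes > 0, log(genes), 0)
  )
}

#' Apply QC thresholds to per-cell metrics
#'
#' A cell passes iff `genes_detected >= min_genes`,
#' `total_counts >= min_counts` and `mito_fraction <= max_mito_fraction`
#' (all boundaries inclusive).
#'
#' @param metrics Tibble from [compute_qc_metrics()].
#' @param thresholds A [qc_thresholds()] object.
#' @return Logical pass vector, one element per row of `metrics`.
#' @export
apply_qc <- function(metrics, thresholds = qc_thresholds()) {
  metrics$genes_detected >= thresholds$min_genes &
    metrics$total_counts >= thresholds$min_counts &
    metrics$mito_fraction <= thresholds$max_mito_fraction
}

#' Flag contaminant cells by marker score
#'
#' A deterministic replacement for embedding-plus-clustering removal of a
#' contaminating population: a cell is flagged when its mean `ln(1 + count)`
#' over the marker genes exceeds the cutoff.
#'
#' @param rna Gene-expression [cell_counts()] matrix.
#' @param marker_genes Marker gene ids; markers absent from the feature list
#'   are dropped with a warning.
#' @param cutoff Score cutoff (strictly greater than flags the cell).
#' @return Logical contaminant mask, one element per cell.
#' @export
flag_contaminants <- function(rna, marker_genes = c("Cd79a", "Cd79b", "Ms4a1"),
                              cutoff = 2) {
  if (!length(marker_genes)) {
    abort("marker gene list is empty", class = "inciteseq_config_error")
  }
  present <- intersect(marker_genes, colnames(rna))
  missing <- setdiff(marker_genes, colnames(rna))
  if (length(missing)) {
    warn(sprintf("contaminant markers absent from features (ignored): %s",
                 paste(missing, collapse = ", ")))
  }
  if (!length(present)) {
    abort("none of the contaminant marker genes are present in the feature list",
          class = "inciteseq_config_error")
  }
  score <- Matrix::rowMeans(log1p(rna[, present, drop = FALSE]))
  as.logical(score > cutoff)
}
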