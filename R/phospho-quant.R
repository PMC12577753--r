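#' Per-group isotype-control medians
#'
#' Computes the median raw isotype-control count per (culture, condition)
#' group over analysable cells (QC-passing, non-contaminant singlets) of the
#' isotype-bearing panel(s). The medians estimate nonspecific antibody
#' background and are subtracted from the phospho-target counts of every
#' cell in the same (culture, condition) group, including cells of panels
#' without their own isotype channel. Even-cardinality medians use the
#' mean-of-the-two-middle-values convention.
#'
#' @param adt ADT [cell_counts()] matrix (phospho targets + isotype).
#' @param annotations Cell annotation tibble with columns `barcode`,
#'   `status`, `condition`, `culture`, `panel`, and optionally `pass_qc`
#'   and `contaminant` (assumed TRUE/FALSE respectively when absent).
#' @param design A [sample_design()].
#' @return A tibble: `culture`, `condition`, `isotype_median`, `n_cells`.
#' @export
compute_isotype_medians <- function(adt, annotations, design) {
  iso_panels <- names(design$panels)[!vapply(design$panels,
                                             function(p) is.null(p$isotype), logical(1))]
  if (!length(iso_panels)) {
    abort("no panel declares an isotype antibody", class = "inciteseq_config_error")
  }
  iso_ab <- unique(unlist(lapply(design$panels[iso_panels], `[[`, "isotype")))
  miss <- setdiff(iso_ab, colnames(adt))
  if (length(miss)) {
    abort(sprintf("isotype antibody '%s' absent from ADT features", miss[[1]]),
          class = "inciteseq_config_error")
  }
  ann <- analysable_cells(annotations)
  ann <- dplyr::filter(ann, .data$panel %in% iso_panels)

  groups <- dplyr::distinct(analysable_cells(annotations),
                            .data$culture, .data$condition)
  iso_counts <- as.numeric(adt[match(ann$barcode, rownames(adt)), iso_ab[[1]]])
  med <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(ann, iso = iso_counts),
                    .data$culture, .data$condition),
    isotype_median = median(.data$iso), n_cells = dplyr::n(), .groups = "drop")
  empty <- dplyr::anti_join(groups, med, by = c("culture", "condition"))
  if (nrow(empty)) {
    abort(sprintf("no isotype-bearing cells for group(s): %s",
                  paste(empty$culture, empty$condition, sep = "_", collapse = ", ")),
          class = "inciteseq_degenerate_error")
  }
  med
}

analysable_cells <- function(annotations) {
  ann <- dplyr::filter(annotations, .data$status == "singlet")
  if ("pass_qc" %in% names(ann)) ann <- dplyr::filter(ann, .data$pass_qc)
  if ("contaminant" %in% names(ann)) ann <- dplyr::filter(ann, !.data$contaminant)
  ann
}

#' Isotype-correct ADT counts and call positivity
#'
#' For each analysable cell and each phospho target of its panel, the
#' corrected level is `v = ln(1 + max(0, a - m))` where `a` is the raw count
#' and `m` the isotype median of the cell's (culture, condition) group; the
#' cell is positive when `v > 0` (equivalently when `a` strictly exceeds
#' `m`). The isotype channel itself is excluded from the output.
#'
#' @param adt ADT [cell_counts()] matrix.
#' @param medians Tibble from [compute_isotype_medians()].
#' @param design A [sample_design()].
#' @param annotations Cell annotation tibble (see
#'   [compute_isotype_medians()]).
#' @return A long tibble: `barcode`, `sample_id`, `culture`, `condition`,
#'   `panel`, `target`, `raw`, `corrected`, `positive`.
#' @export
correct_and_call <- function(adt, medians, design, annotations) {
  ann <- analysable_cells(annotations)
  ann <- dplyr::left_join(ann, medians, by = c("culture", "condition"))
  if (anyNA(ann$isotype_median)) {
    abort("some cells belong to a (culture, condition) group with no isotype median",
          class = "inciteseq_config_error")
  }
  per_panel <- lapply(split(ann, ann$panel), function(a) {
    targets <- design$panels[[a$panel[[1]]]]$phospho
    miss <- setdiff(targets, colnames(adt))
    if (length(miss)) {
      abort(sprintf("panel target(s) absent from ADT features: %s",
                    paste(miss, collapse = ", ")),
            class = "inciteseq_config_error")
    }
    raw <- as.matrix(adt[match(a$barcode, rownames(adt)), targets, drop = FALSE])
    purrr::map_dfr(targets, function(tg) {
      v <- log1p(pmax(0, raw[, tg] - a$isotype_median))
      tibble::tibble(barcode = a$barcode, sample_id = a$sample_id,
                     culture = a$culture, condition = a$condition,
                     panel = a$panel, target = tg,
                     raw = unname(raw[, tg]), corrected = unname(v),
                     positive = unname(v > 0))
    })
  })
  dplyr::bind_rows(per_panel)
}

#' Combinatorial phospho-state annotation
#'
#' For each cell of a two-target panel: both targets positive -> `"double"`;
#' exactly one -> `"single:<target>"`; neither -> `"unphosphorylated"`.
#'
#' @param quant Tibble from [correct_and_call()].
#' @param design A [sample_design()]; every panel appearing in `quant` must
#'   declare exactly two phospho targets.
#' @return A tibble: `barcode`, `sample_id`, `culture`, `condition`,
#'   `panel`, `state`.
#' @export
annotate_phospho_states <- function(quant, design) {
  for (p in unique(quant$panel)) {
    if (length(design$panels[[p]]$phospho) != 2L) {
      abort(sprintf(
        "panel '%s' declares %d phospho targets; the combinatorial scheme needs exactly 2",
        p, length(design$panels[[p]]$phospho)),
        class = "inciteseq_config_error")
    }
  }
  wide <- dplyr::summarise(
    dplyr::group_by(quant, .data$barcode, .data$sample_id, .data$culture,
                    .data$condition, .data$panel),
    n_pos = sum(.data$positive),
    pos_target = if (sum(.data$positive) == 1L) .data$target[.data$positive] else NA_character_,
    .groups = "drop")
  dplyr::transmute(wide,
    .data$barcode, .data$sample_id, .data$culture, .data$condition, .data$panel,
    state = dplyr::case_when(
      n_pos == 2L ~ "double",
      n_pos == 1L ~ paste0("single:", pos_target),
      TRUE ~ "unphosphorylated"
    ))
}

#' Per-sample positivity and magnitude summaries
#'
#' Percent positivity and mean corrected level per (culture, condition,
#' target); denominators are the analysable cells of that sample. Because
#' every target is carried by exactly one panel, (culture, condition)
#' identifies the sample for a given target; `sample_id` is
#' `<culture>_<condition>` to match flow-cytometry summary keys.
#'
#' @param quant Tibble from [correct_and_call()].
#' @return A tibble: `sample_id`, `culture`, `condition`, `panel`,
#'   `target_id`, `percent_positive`, `mean_corrected`, `n_cells`. Samples
#'   with no cells are absent (and warned about upstream when expected).
#' @export
summarize_per_sample <- function(quant) {
  dplyr::summarise(
    dplyr::group_by(quant, .data$culture, .data$condition, .data$panel,
                    target_id = .data$target),
    percent_positive = 100 * mean(.data$positive),
    mean_corrected = mean(.data$corrected),
    n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sample_id = paste(.data$culture, .data$condition, sep = "_"),
                  .before = 1L)
}
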