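#' Build signed DEG sets from differential-expression tables
#'
#' From each named table, keep the genes with `p_adj < alpha` (and past the
#' fold-change threshold when the tables carry one in `is_deg`) as
#' (gene, direction) pairs, direction up or down.
#'
#' @param tables Named list of [hurdle_de()] tables (or any data frame with
#'   `gene`, `p_adj`, `direction` columns).
#' @param alpha Adjusted-p cutoff.
#' @return A tibble: `set`, `gene`, `direction` — one row per signed member.
#' @export
build_signed_sets <- function(tables, alpha = 0.05) {
  if (is.null(names(tables)) || any(names(tables) == "") ||
      anyDuplicated(names(tables))) {
    abort("tables must have unique non-empty names", class = "inciteseq_config_error")
  }
  out <- purrr::imap_dfr(tables, function(tb, nm) {
    keep <- !is.na(tb$p_adj) & tb$p_adj < alpha
    tibble::tibble(set = nm, gene = tb$gene[keep], direction = tb$direction[keep])
  })
  bad <- dplyr::count(out, .data$set, .data$gene)
  bad <- dplyr::filter(bad, .data$n > 1)
  if (nrow(bad)) {
    abort(sprintf("gene(s) appearing with both directions inside one set: %s",
                  paste(unique(bad$gene), collapse = ", ")),
          class = "inciteseq_config_error")
  }
  out
}

#' Partition signed gene sets into exclusive intersection signatures
#'
#' Every (gene, direction) pair in the union of the input sets is assigned
#' to exactly one signature: the exact family of sets that contain it
#' (upset-plot semantics). A gene significant up in one set and down in
#' another contributes two distinct elements. Signatures are ordered by
#' size (descending), then lexicographically by signature label.
#'
#' @param sets A tibble from [build_signed_sets()] (columns `set`, `gene`,
#'   `direction`).
#' @return A tibble of class `gene_set_partition`: `signature`
#'   (`&`-joined set names), `n_sets`, `size`, `members` (list column of
#'   `gene(direction)` strings).
#' @export
intersect_sets <- function(sets) {
  stopifnot(all(c("set", "gene", "direction") %in% names(sets)))
  if (!nrow(sets)) {
    out <- tibble::tibble(signature = character(), n_sets = integer(),
                          size = integer(), members = list())
    class(out) <- c("gene_set_partition", class(out))
    return(out)
  }
  set_levels <- sort(unique(sets$set))
  elems <- dplyr::summarise(
    dplyr::group_by(sets, .data$gene, .data$direction),
    signature = paste(sort(unique(.data$set)), collapse = "&"),
    .groups = "drop")
  out <- dplyr::summarise(
    dplyr::group_by(elems, .data$signature),
    n_sets = lengths(strsplit(.data$signature[[1]], "&", fixed = TRUE)),
    size = dplyr::n(),
    members = list(paste0(.data$gene, "(", .data$direction, ")")),
    .groups = "drop")
  out <- dplyr::arrange(out, dplyr::desc(.data$size), .data$signature)
  attr(out, "set_names") <- set_levels
  class(out) <- c("gene_set_partition", class(out))
  out
}

#' @method glance gene_set_partition
#' @export
glance.gene_set_partition <- function(x, ...) {
  tibble::tibble(n_signatures = nrow(x),
                 n_elements = sum(x$size),
                 n_sets = length(attr(x, "set_names")))
}
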