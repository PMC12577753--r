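#' Multiplexed sample design
#'
#' Describes how hashtag oligos encode samples. Two disjoint hashtag groups
#' are used: condition hashes (stimulated vs. unstimulated) and identity
#' hashes, each of which marks one (culture, antibody panel) combination.
#' A sample is a condition x culture x panel combination.
#'
#' @param condition_hashes Named character vector: hashtag id -> condition
#'   label.
#' @param identity_hashes Data frame with columns `hashtag`, `culture`,
#'   `panel`.
#' @param panels Named list, one entry per panel label, each a list with
#'   `phospho` (character vector of phospho-target antibody ids) and
#'   optionally `isotype` (isotype-control antibody id or `NULL`).
#' @return A `sample_design` object.
#' @export
sample_design <- function(condition_hashes, identity_hashes, panels) {
  identity_hashes <- tibble::as_tibble(identity_hashes)
  stopifnot(all(c("hashtag", "culture", "panel") %in% names(identity_hashes)))
  if (length(intersect(names(condition_hashes), identity_hashes$hashtag))) {
    abort("condition and identity hashtag sets must be disjoint",
          class = "inciteseq_config_error")
  }
  missing_panels <- setdiff(identity_hashes$panel, names(panels))
  if (length(missing_panels)) {
    abort(sprintf("identity hashes reference undeclared panels: %s",
                  paste(missing_panels, collapse = ", ")),
          class = "inciteseq_config_error")
  }
  structure(list(condition_hashes = condition_hashes,
                 identity_hashes = identity_hashes,
                 panels = panels),
            class = "sample_design")
}

#' The default two-condition, three-culture, two-panel hashing design
#'
#' Hashtag1/2 mark unstimulated/stimulated condition; Hashtags 3-5 mark
#' cultures A-C of panel 1 and Hashtags 6-8 cultures A-C of panel 2.
#' Panel 1 carries p-STAT3 and p-p65 plus the rabbit isotype control;
#' panel 2 carries p-ERK1/2 and p-FOS (no isotype). The Cartesian product
#' gives 12 unique samples.
#'
#' @return A [sample_design()] object.
#' @export
default_sample_design <- function() {
  sample_design(
    condition_hashes = c(Hashtag1 = "unstimulated", Hashtag2 = "stimulated"),
    identity_hashes = tibble::tibble(
      hashtag = paste0("Hashtag", 3:8),
      culture = rep(paste0("culture", c("A", "B", "C")), 2),
      panel   = rep(c("panel1", "panel2"), each = 3)
    ),
    panels = list(
      panel1 = list(phospho = c("p-STAT3", "p-p65"), isotype = "isotype"),
      panel2 = list(phospho = c("p-ERK1/2", "p-FOS"), isotype = NULL)
    )
  )
}

#' @export
print.sample_design <- function(x, ...) {
  cat(sprintf("<sample_design> %d condition hashes x %d identity hashes -> %d samples\n",
              length(x$condition_hashes), nrow(x$identity_hashes),
              nrow(enumerate_valid_samples(x))))
  invisible(x)
}

#' Enumerate the valid sample identities of a design
#'
#' The Cartesian product of condition labels and identity hashes (each of
#' which fixes a culture and a panel), in deterministic order (panel, then
#' culture, then condition as declared).
#'
#' @param design A [sample_design()].
#' @return A tibble with columns `sample_id`, `condition`, `culture`,
#'   `panel`.
#' @export
enumerate_valid_samples <- function(design) {
  stopifnot(inherits(design, "sample_design"))
  if (!nrow(design$identity_hashes) || !length(design$condition_hashes)) {
    return(tibble::tibble(sample_id = character(), condition = character(),
                          culture = character(), panel = character()))
  }
  grid <- tidyr::crossing(
    design$identity_hashes[c("culture", "panel")],
    condition = unname(design$condition_hashes)
  )
  grid <- dplyr::distinct(grid)
  grid <- dplyr::arrange(grid, .data$panel, .data$culture, .data$condition)
  dplyr::transmute(grid,
    sample_id = paste(.data$culture, .data$condition, .data$panel, sep = "_"),
    condition = .data$condition, culture = .data$culture, panel = .data$panel)
}

#' Estimate per-hashtag positive-staining cutoffs
#'
#' A reproducible stand-in for visual histogram gating. The default method
#' splits `ln(1 + count)` of each hashtag into two classes by exact 1-D
#' two-means and places the threshold at the midpoint of the class centres
#' (back-transformed to the count scale). Alternatives: `"quantile"` (a fixed
#' quantile of the log counts) and `"otsu"` (maximal between-class variance
#' on a 256-bin histogram of log counts). Cells with count >= cutoff are
#' positive.
#'
#' @param hto Hashtag [cell_counts()] matrix.
#' @param method `"twomeans"` (default), `"quantile"` or `"otsu"`.
#' @param manual Optional named numeric vector of cutoffs that override the
#'   estimates verbatim.
#' @param quantile_prob Probability used by the quantile method.
#' @return Named numeric vector of cutoffs on the raw count scale.
#' @export
estimate_hash_cutoffs <- function(hto, method = c("twomeans", "quantile", "otsu"),
                                  manual = NULL, quantile_prob = 0.5) {
  method <- match.arg(method)
  cutoffs <- setNames(numeric(ncol(hto)), colnames(hto))
  for (h in colnames(hto)) {
    if (!is.null(manual) && h %in% names(manual)) {
      cutoffs[[h]] <- manual[[h]]
      next
    }
    v <- log1p(as.numeric(hto[, h]))
    if (length(unique(v)) < 2) {
      abort(sprintf("hashtag '%s' has a constant count distribution; supply a manual cutoff", h),
            class = "inciteseq_degenerate_error")
    }
    mid <- switch(method,
      twomeans = two_means_split(v),
      quantile = unname(quantile(v, quantile_prob)),
      otsu     = otsu_split(v)
    )
    cutoffs[[h]] <- expm1(mid)
  }
  cutoffs
}

# exact 1-D two-means: scan all sorted split points, minimise within-class SS;
# returns the midpoint of the two class means
two_means_split <- function(v) {
  s <- sort(v)
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  k <- seq_len(n - 1)
  ss_left <- cs2[k] - cs[k]^2 / k
  nr <- n - k
  sum_r <- cs[n] - cs[k]
  ss_right <- (cs2[n] - cs2[k]) - sum_r^2 / nr
  best <- which.min(ss_left + ss_right)
  (cs[best] / best + sum_r[best] / nr[best]) / 2
}

otsu_split <- function(v, nbins = 256L) {
  br <- seq(min(v), max(v), length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  wt <- w[nbins]
  mut <- mu[nbins]
  valid <- w > 0 & w < wt
  between <- rep(-Inf, nbins)
  between[valid] <- (mut * w[valid] - wt * mu[valid])^2 /
    (w[valid] * (wt - w[valid]))
  mids[which.max(between)]
}

#' Classify cells from hashtag counts
#'
#' Applies the cutoff-based rules: a cell is a doublet if it is positive for
#' two or more identity hashes, or for both condition hashes; unassigned if
#' it has no positive identity hash or no positive condition hash; otherwise
#' a singlet assigned to the sample composed from its unique positive
#' condition and identity hashes. Positivity is count >= cutoff (inclusive).
#'
#' @param hto Hashtag [cell_counts()] matrix.
#' @param cutoffs Named numeric vector covering every hashtag in `design`
#'   (see [estimate_hash_cutoffs()]).
#' @param design A [sample_design()].
#' @return A tibble (one row per cell): `barcode`, `status`
#'   (singlet/doublet/unassigned), `sample_id`, `condition`, `culture`,
#'   `panel`, `n_condition_pos`, `n_identity_pos`, `positive_hashes`
#'   (comma-separated). The cutoffs used are attached as attribute
#'   `"cutoffs"`.
#' @export
classify_cells <- function(hto, cutoffs, design) {
  stopifnot(inherits(design, "sample_design"))
  design_hashes <- c(names(design$condition_hashes), design$identity_hashes$hashtag)
  unknown <- setdiff(colnames(hto), design_hashes)
  if (length(unknown)) {
    abort(sprintf("hashtags present in counts but absent from design: %s",
                  paste(unknown, collapse = ", ")),
          class = "inciteseq_config_error")
  }
  missing_cut <- setdiff(colnames(hto), names(cutoffs))
  if (length(missing_cut)) {
    abort(sprintf("no cutoff for hashtags: %s", paste(missing_cut, collapse = ", ")),
          class = "inciteseq_config_error")
  }
  if (nrow(hto) == 0L) {
    res <- tibble::tibble(barcode = character(), status = character(),
                          sample_id = character(), condition = character(),
                          culture = character(), panel = character(),
                          n_condition_pos = integer(), n_identity_pos = integer(),
                          positive_hashes = character())
    attr(res, "cutoffs") <- cutoffs
    return(res)
  }

  hashes <- colnames(hto)
  pos <- as.matrix(hto) >= rep(cutoffs[hashes], each = nrow(hto))
  cond_hashes <- intersect(hashes, names(design$condition_hashes))
  id_hashes <- intersect(hashes, design$identity_hashes$hashtag)
  n_cond <- rowSums(pos[, cond_hashes, drop = FALSE])
  n_id <- rowSums(pos[, id_hashes, drop = FALSE])

  status <- dplyr::case_when(
    n_id >= 2 | n_cond >= 2 ~ "doublet",
    n_id == 0 | n_cond == 0 ~ "unassigned",
    TRUE ~ "singlet"
  )

  # singlet sample composition
  cond_lab <- rep(NA_character_, nrow(hto))
  cult <- rep(NA_character_, nrow(hto))
  pan <- rep(NA_character_, nrow(hto))
  is_s <- status == "singlet"
  if (any(is_s)) {
    cond_idx <- max.col(pos[, cond_hashes, drop = FALSE], ties.method = "first")
    id_idx <- max.col(pos[, id_hashes, drop = FALSE], ties.method = "first")
    cond_lab[is_s] <- unname(design$condition_hashes[cond_hashes])[cond_idx[is_s]]
    id_tab <- design$identity_hashes[match(id_hashes, design$identity_hashes$hashtag), ]
    cult[is_s] <- id_tab$culture[id_idx[is_s]]
    pan[is_s] <- id_tab$panel[id_idx[is_s]]
  }
  res <- tibble::tibble(
    barcode = rownames(hto),
    status = status,
    sample_id = ifelse(is_s, paste(cult, cond_lab, pan, sep = "_"), NA_character_),
    condition = cond_lab, culture = cult, panel = pan,
    n_condition_pos = as.integer(n_cond),
    n_identity_pos = as.integer(n_id),
    positive_hashes = apply(pos, 1L, function(p) paste(hashes[p], collapse = ","))
  )
  attr(res, "cutoffs") <- cutoffs
  res
}
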