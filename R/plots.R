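#' Hashtag count histograms with cutoffs
#'
#' Per-hashtag histograms of `ln(1 + count)` with the estimated positive
#' staining cutoff drawn as a vertical line — the plot a visual gater would
#' have looked at.
#'
#' @param hto Hashtag [cell_counts()] matrix.
#' @param cutoffs Named cutoff vector from [estimate_hash_cutoffs()].
#' @return A ggplot object.
#' @export
plot_hash_cutoffs <- function(hto, cutoffs) {
  df <- tibble::tibble(
    hashtag = rep(colnames(hto), each = nrow(hto)),
    log_count = log1p(as.numeric(as.matrix(hto)))
  )
  cuts <- tibble::tibble(hashtag = names(cutoffs), cut = log1p(unname(cutoffs)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_count)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::geom_vline(data = cuts, ggplot2::aes(xintercept = .data$cut),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~hashtag) +
    ggplot2::labs(x = "ln(1 + hashtag count)", y = "cells")
}

#' Corrected phospho-level distributions
#'
#' Density of the isotype-corrected, log-transformed phospho levels per
#' target, split by condition.
#'
#' @param quant Tibble from [correct_and_call()].
#' @return A ggplot object.
#' @export
plot_phospho_levels <- function(quant) {
  ggplot2::ggplot(quant, ggplot2::aes(x = .data$corrected,
                                      fill = .data$condition)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~target, scales = "free_y") +
    ggplot2::labs(x = "ln(1 + isotype-corrected count)", y = "density")
}

#' Volcano plot of a differential-expression table
#'
#' @param object An [hurdle_de()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot incite_de
#' @export
autoplot.incite_de <- function(object, ...) {
  df <- tidy(object)
  df$neglog10p <- -log10(pmax(df$p_adj, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$logFC_ln, y = .data$neglog10p,
                                   colour = .data$is_deg)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "log fold change (natural log scale)",
                  y = "-log10 adjusted p", colour = "DEG")
}

#' Intersection-signature size plot
#'
#' A bar rendering of the exclusive gene-set partition (the quantity an
#' upset plot displays).
#'
#' @param object A [intersect_sets()] partition.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gene_set_partition
#' @export
autoplot.gene_set_partition <- function(object, ...) {
  df <- tidy(object)
  df$signature <- factor(df$signature, levels = rev(df$signature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "signed genes in exclusive signature", y = NULL)
}

#' @method tidy gene_set_partition
#' @export
tidy.gene_set_partition <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gene_set_partition")
  out
}

#' Sequencing-vs-flow concordance scatter
#'
#' One panel per target: flow percent positivity against sequencing percent
#' positivity, with the least-squares line.
#'
#' @param seq_summary Tibble from [summarize_per_sample()].
#' @param flow Flow summary tibble.
#' @return A ggplot object.
#' @export
plot_concordance <- function(seq_summary, flow) {
  joined <- dplyr::inner_join(seq_summary, flow,
                              by = c("sample_id", "target_id"),
                              suffix = c("_seq", "_flow"))
  ggplot2::ggplot(joined, ggplot2::aes(x = .data$percent_positive_seq,
                                       y = .data$percent_positive_flow)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~target_id) +
    ggplot2::labs(x = "sequencing percent positive", y = "flow percent positive")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
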