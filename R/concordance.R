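#' Simple least-squares fit
#'
#' Ordinary least squares of `y` on `x` with closed-form slope and
#' intercept, `R^2 = 1 - SS_res / SS_tot`, and an F-test p-value for the
#' slope (F with 1 and n-2 degrees of freedom, defined when n >= 3).
#'
#' @param x,y Numeric vectors of equal length (n >= 2); `x` must not be
#'   constant.
#' @return A one-row tibble: `n`, `slope`, `intercept`, `r_squared`, `p`.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "inciteseq_config_error")
  }
  n <- length(x)
  if (n < 2) abort("need at least 2 points", class = "inciteseq_degenerate_error")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    abort("x is constant; regression is degenerate",
          class = "inciteseq_degenerate_error")
  }
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  p <- NA_real_
  if (n >= 3) {
    if (ss_res == 0) {
      p <- if (ss_tot == 0) NA_real_ else 0
    } else {
      f <- (ss_tot - ss_res) / (ss_res / (n - 2))
      p <- pf(f, 1, n - 2, lower.tail = FALSE)
    }
  }
  tibble::tibble(n = n, slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)), p = p)
}

#' Sequencing-vs-flow concordance regressions
#'
#' Joins the per-sample sequencing summary with the flow-cytometry summary
#' on (sample, target) and fits, per target, one regression for percent
#' positivity (flow percent on sequencing percent) and one for signal
#' magnitude (flow MFI on sequencing mean corrected level). Sequencing is
#' the predictor; R-squared, the quantity of interest, does not depend on
#' the orientation. Targets with fewer than 3 shared samples are skipped
#' with a warning; unmatched keys are reported and dropped.
#'
#' @param seq_summary Tibble from [summarize_per_sample()] (or
#'   [truth_sample_summary()]).
#' @param flow Flow summary tibble (see [read_flow_table()]).
#' @return A tibble of class `concordance_fits`: `target_id`, `axis`
#'   (`"percent_positive"` or `"magnitude"`), `n`, `slope`, `intercept`,
#'   `r_squared`, `p`.
#' @export
compare_modalities <- function(seq_summary, flow) {
  flow <- validate_flow_table(flow)
  joined <- dplyr::inner_join(seq_summary, flow, by = c("sample_id", "target_id"),
                              suffix = c("_seq", "_flow"))
  n_drop <- nrow(seq_summary) - nrow(joined)
  if (n_drop > 0) {
    warn(sprintf("%d sequencing summary row(s) had no matching flow row and were dropped",
                 n_drop))
  }
  fits <- purrr::map_dfr(split(joined, joined$target_id), function(d) {
    tg <- d$target_id[[1]]
    if (nrow(d) < 3) {
      warn(sprintf("target '%s' has fewer than 3 shared samples; skipped", tg))
      return(tibble::tibble())
    }
    dplyr::bind_rows(
      dplyr::mutate(fit_linear(d$percent_positive_seq, d$percent_positive_flow),
                    target_id = tg, axis = "percent_positive", .before = 1L),
      dplyr::mutate(fit_linear(d$mean_corrected, d$mfi),
                    target_id = tg, axis = "magnitude", .before = 1L)
    )
  })
  class(fits) <- c("concordance_fits", class(fits))
  fits
}

#' @method tidy concordance_fits
#' @export
tidy.concordance_fits <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "concordance_fits")
  out
}
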