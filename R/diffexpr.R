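#' Differential-expression settings
#'
#' @param min_pct Genes are tested only if detected in at least this
#'   fraction of cells in one of the two groups (default 0.01, i.e. genes
#'   expressed in under 1% of cells are excluded).
#' @param logfc_threshold Minimum absolute log fold change for DEG
#'   membership (default 0: no fold-change filtering).
#' @param alpha Adjusted-p cutoff for DEG membership.
#' @param min_cells Minimum cells per group.
#' @param ridge Ridge penalty stabilising separated logistic fits.
#' @return A `de_settings` list.
#' @export
de_settings <- function(min_pct = 0.01, logfc_threshold = 0, alpha = 0.05,
                        min_cells = 20L, ridge = 1e-8) {
  stopifnot(min_pct >= 0, min_pct <= 1, alpha > 0, alpha < 1)
  structure(list(min_pct = min_pct, logfc_threshold = logfc_threshold,
                 alpha = alpha, min_cells = as.integer(min_cells),
                 ridge = ridge), class = "de_settings")
}

#' Cluster-wise size factors
#'
#' Within each cluster, a cell's factor is its library size divided by the
#' cluster mean library size. Clusters are then rescaled by the median
#' ratio of their per-cell mean pseudo-bulk profile to the overall per-cell
#' mean pseudo-bulk (genes with zero overall sum excluded), and the whole
#' vector is rescaled to mean 1.
#'
#' @param rna Gene-expression [cell_counts()] matrix.
#' @param cluster_labels Vector of cluster labels, one per cell; every
#'   cluster must have at least 2 cells.
#' @return Named numeric vector of size factors (mean 1).
#' @export
compute_size_factors <- function(rna, cluster_labels) {
  stopifnot(length(cluster_labels) == nrow(rna))
  lib <- Matrix::rowSums(rna)
  if (any(lib == 0)) {
    abort("all-zero cells present; remove them with QC before normalization",
          class = "inciteseq_degenerate_error")
  }
  cl <- as.character(cluster_labels)
  sizes <- table(cl)
  if (any(sizes < 2)) {
    abort(sprintf("cluster(s) with fewer than 2 cells: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "inciteseq_degenerate_error")
  }
  overall <- Matrix::colMeans(rna)
  keep <- overall > 0
  s <- numeric(nrow(rna))
  for (k in unique(cl)) {
    idx <- cl == k
    s[idx] <- lib[idx] / mean(lib[idx])
    pb <- Matrix::colMeans(rna[idx, , drop = FALSE])
    s[idx] <- s[idx] * median(pb[keep] / overall[keep])
  }
  s <- s / mean(s)
  names(s) <- rownames(rna)
  s
}

#' Size-factor log-normalization
#'
#' `y = ln(1 + a / s_c)`: each cell's counts are divided by its size factor
#' and natural-log(1+x) transformed. Zeros map to zeros, so sparsity is
#' preserved.
#'
#' @param rna Gene-expression [cell_counts()] matrix.
#' @param size_factors Positive numeric vector aligned to cells.
#' @return A sparse cells x genes matrix of normalized expression.
#' @export
normalize_counts <- function(rna, size_factors) {
  stopifnot(length(size_factors) == nrow(rna), all(size_factors > 0))
  scaled <- Matrix::Diagonal(x = 1 / size_factors) %*% rna
  y <- log1p(methods::as(scaled, "CsparseMatrix"))
  dimnames(y) <- dimnames(rna)
  y
}

# deviance of a ridge-penalised logistic regression (IRLS)
ridge_logistic_deviance <- function(X, y, lambda = 1e-8, maxit = 60L, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  dev <- NA_real_
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    H <- XtW %*% X + diag(lambda, p)
    beta_new <- tryCatch(drop(solve(H, XtW %*% z)), error = function(e) NULL)
    if (is.null(beta_new)) return(NA_real_)
    beta <- beta_new
    mu <- pmin(pmax(stats::plogis(drop(X %*% beta)), 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev - dev_old) < tol * (abs(dev) + 1)) break
    dev_old <- dev
  }
  dev
}

gaussian_rss <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  aliased <- is.na(fit$coefficients)
  list(rss = sum(fit$residuals^2), aliased = aliased, rank = fit$rank)
}

#' Two-part (hurdle) differential-expression test
#'
#' For each gene, combines a detection component (ridge-stabilised logistic
#' regression of `y > 0` on the group indicator plus covariates, versus the
#' covariate-only null) with a positive-expression component (Gaussian
#' linear model of `y` on group plus covariates over detected cells only).
#' The combined statistic is the sum of the two likelihood-ratio statistics,
#' referred to a chi-square with one degree of freedom per estimable
#' component. The log fold change is the difference of group means of the
#' log-normalized expression (natural-log scale), and detection fractions
#' are reported per group. Benjamini-Hochberg adjustment is applied over
#' tested genes; a gene is a DEG when `p_adj < alpha` and
#' `|logFC| > logfc_threshold`.
#'
#' @param y Normalized expression (cells x genes) from
#'   [normalize_counts()].
#' @param group_a,group_b Disjoint logical masks (or barcode vectors) over
#'   cells.
#' @param covariates Optional numeric matrix/data.frame of per-cell
#'   covariates (e.g. natural-log genes detected), aligned to the rows of
#'   `y`.
#' @param settings A [de_settings()] object.
#' @return A tibble of class `incite_de`: `gene`, `logFC_ln`, `pct_A`,
#'   `pct_B`, `stat`, `df`, `p`, `p_adj`, `direction`, `is_deg`.
#' @export
hurdle_de <- function(y, group_a, group_b, covariates = NULL,
                      settings = de_settings()) {
  if (is.character(group_a)) group_a <- rownames(y) %in% group_a
  if (is.character(group_b)) group_b <- rownames(y) %in% group_b
  stopifnot(length(group_a) == nrow(y), length(group_b) == nrow(y))
  if (any(group_a & group_b)) {
    abort("groups must be disjoint", class = "inciteseq_config_error")
  }
  if (sum(group_a) < settings$min_cells || sum(group_b) < settings$min_cells) {
    abort(sprintf("each group needs at least %d cells", settings$min_cells),
          class = "inciteseq_degenerate_error")
  }
  sel <- group_a | group_b
  ys <- y[sel, , drop = FALSE]
  grp <- as.numeric(group_a[sel])
  cov <- NULL
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    stopifnot(nrow(cov) == nrow(y))
    cov <- cov[sel, , drop = FALSE]
    if (any(!is.finite(cov))) {
      abort("covariate values must be finite", class = "inciteseq_config_error")
    }
  }
  n <- nrow(ys)
  X0 <- cbind(intercept = rep(1, n), cov)
  X1 <- cbind(X0, group = grp)

  a_idx <- grp == 1
  pct_a <- unname(Matrix::colMeans(ys[a_idx, , drop = FALSE] > 0))
  pct_b <- unname(Matrix::colMeans(ys[!a_idx, , drop = FALSE] > 0))
  logfc <- unname(Matrix::colMeans(ys[a_idx, , drop = FALSE]) -
    Matrix::colMeans(ys[!a_idx, , drop = FALSE]))

  tested <- pmax(pct_a, pct_b) >= settings$min_pct
  genes <- colnames(ys)

  stat <- df <- rep(NA_real_, ncol(ys))
  for (g in which(tested)) {
    yg <- as.numeric(ys[, g])
    det <- yg > 0
    lr_d <- NA_real_
    if (any(det) && !all(det)) {
      d0 <- ridge_logistic_deviance(X0, as.numeric(det), settings$ridge)
      d1 <- ridge_logistic_deviance(X1, as.numeric(det), settings$ridge)
      if (!is.na(d0) && !is.na(d1)) lr_d <- max(0, d0 - d1)
    }
    lr_c <- NA_real_
    nd <- sum(det)
    if (nd >= ncol(X1) + 2 && length(unique(grp[det])) == 2) {
      f1 <- gaussian_rss(X1[det, , drop = FALSE], yg[det])
      if (!f1$aliased[["group"]]) {
        f0 <- gaussian_rss(X0[det, , drop = FALSE], yg[det])
        rss1 <- max(f1$rss, 1e-300)
        lr_c <- max(0, nd * (log(max(f0$rss, 1e-300)) - log(rss1)))
      }
    }
    comp <- c(lr_d, lr_c)
    k <- sum(!is.na(comp))
    if (k > 0) {
      stat[g] <- sum(comp, na.rm = TRUE)
      df[g] <- k
    }
  }
  p <- ifelse(is.na(stat), NA_real_, pchisq(stat, df, lower.tail = FALSE))
  p[!tested] <- NA_real_
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")

  res <- tibble::tibble(
    gene = genes,
    logFC_ln = logfc,
    pct_A = pct_a, pct_B = pct_b,
    stat = stat, df = df, p = p, p_adj = p_adj,
    direction = ifelse(logfc > 0, "up", "down"),
    is_deg = !is.na(p_adj) & p_adj < settings$alpha &
      abs(logfc) > settings$logfc_threshold
  )
  res <- res[tested, , drop = FALSE]
  class(res) <- c("incite_de", class(res))
  attr(res, "settings") <- settings
  attr(res, "n_cells") <- c(A = sum(a_idx), B = sum(!a_idx))
  res
}

#' @method glance incite_de
#' @export
glance.incite_de <- function(x, ...) {
  tibble::tibble(
    n_genes_tested = nrow(x),
    n_deg = sum(x$is_deg, na.rm = TRUE),
    n_up = sum(x$is_deg & x$direction == "up", na.rm = TRUE),
    n_down = sum(x$is_deg & x$direction == "down", na.rm = TRUE),
    n_cells_A = attr(x, "n_cells")[["A"]],
    n_cells_B = attr(x, "n_cells")[["B"]]
  )
}

#' @method tidy incite_de
#' @export
tidy.incite_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "incite_de")
  out
}
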