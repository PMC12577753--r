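test_that("single-cluster size factors reduce to library scaling", {
  m <- make_counts(rbind(c(60, 40), c(180, 120)), cells = c("a", "b"))
  s <- compute_size_factors(m, c("k", "k"))
  expect_equal(unname(s), c(0.5, 1.5))

  same <- make_counts(matrix(5, 4, 3))
  expect_equal(unname(compute_size_factors(same, rep("k", 4))), rep(1, 4))
})

test_that("size factors match an independent brute-force implementation", {
  set.seed(14)
  m <- matrix(rpois(100, 5), 10, 10,
              dimnames = list(sprintf("c%d", 1:10), sprintf("g%d", 1:10)))
  labels <- rep(c("k1", "k2"), each = 5)
  s <- compute_size_factors(cell_counts(m, "gene"), labels)

  # brute force, written independently from the package internals
  lib <- rowSums(m)
  overall <- colMeans(m)
  keep <- overall > 0
  sb <- numeric(10)
  for (k in c("k1", "k2")) {
    idx <- labels == k
    pb <- colMeans(m[idx, ])
    sb[idx] <- (lib[idx] / mean(lib[idx])) * median(pb[keep] / overall[keep])
  }
  sb <- sb / mean(sb)
  expect_equal(unname(s), unname(sb), tolerance = 1e-12)
})

test_that("size factors reject degenerate inputs", {
  m <- make_counts(rbind(c(1, 1), c(0, 0)))
  expect_error(compute_size_factors(m, c("k", "k")),
               class = "inciteseq_degenerate_error")
  m2 <- make_counts(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_error(compute_size_factors(m2, c("k1", "k1", "k2")),
               class = "inciteseq_degenerate_error")
})

test_that("log-normalization follows y = ln(1 + a/s)", {
  m <- Matrix::Matrix(rbind(c(0, exp(1) - 1), c(4, 0)), sparse = TRUE,
                      dimnames = list(c("a", "b"), c("g1", "g2")))
  y <- normalize_counts(m, c(1, 2))
  expect_equal(y["a", 1], 0)
  expect_equal(y["a", 2], 1)
  expect_equal(y["b", 1], log1p(2))
  # doubling all size factors decreases every nonzero value
  y2 <- normalize_counts(m, c(2, 4))
  nz <- as.matrix(y) > 0
  expect_true(all(as.matrix(y2)[nz] < as.matrix(y)[nz]))
})

make_norm <- function(n_per_group = 60, n_genes = 30, seed = 1,
                      shift_genes = integer(), shift = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  counts <- matrix(rnbinom(n * n_genes, size = 2, mu = 3), n, n_genes,
                   dimnames = list(sprintf("c%d", 1:n), sprintf("g%d", 1:n_genes)))
  grp_a <- c(rep(TRUE, n_per_group), rep(FALSE, n_per_group))
  if (length(shift_genes)) {
    counts[grp_a, shift_genes] <-
      matrix(rnbinom(n_per_group * length(shift_genes), size = 2,
                     mu = 3 * exp(shift)), n_per_group)
  }
  y <- log1p(counts)
  list(y = Matrix::Matrix(y, sparse = TRUE), a = grp_a, b = !grp_a)
}

test_that("logFC is the difference of group means and directions follow it", {
  d <- make_norm(seed = 3, shift_genes = 1:3, shift = 1.5)
  res <- hurdle_de(d$y, d$a, d$b)
  manual <- colMeans(as.matrix(d$y)[d$a, res$gene]) -
    colMeans(as.matrix(d$y)[d$b, res$gene])
  expect_equal(res$logFC_ln, unname(manual))
  expect_equal(res$direction, ifelse(res$logFC_ln > 0, "up", "down"))
  expect_true(all(res$gene[1:3] %in% res$gene[res$is_deg]))
})

test_that("genes below min_pct in both groups are excluded", {
  d <- make_norm(n_per_group = 200, seed = 4)
  y <- as.matrix(d$y)
  y[, 1] <- 0
  y[1, 1] <- 2           # 0.5% detection in one group only
  res <- hurdle_de(Matrix::Matrix(y, sparse = TRUE), d$a, d$b,
                   settings = de_settings(min_pct = 0.01))
  expect_false("g1" %in% res$gene)
})

test_that("complete separation falls back to the discrete component", {
  d <- make_norm(n_per_group = 40, seed = 5)
  y <- as.matrix(d$y)
  y[, 2] <- 0
  y[d$a, 2] <- 2          # detected in 100% of A, 0% of B
  res <- hurdle_de(Matrix::Matrix(y, sparse = TRUE), d$a, d$b)
  row <- res[res$gene == "g2", ]
  expect_equal(row$logFC_ln, 2)
  expect_equal(row$df, 1)
  expect_lt(row$p, 1e-10)
  expect_equal(row$direction, "up")
})

test_that("swapping groups negates logFC and preserves p-values", {
  d <- make_norm(seed = 6, shift_genes = 1:2)
  r1 <- hurdle_de(d$y, d$a, d$b)
  r2 <- hurdle_de(d$y, d$b, d$a)
  expect_equal(r1$logFC_ln, -r2$logFC_ln)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)
})

test_that("BH adjustment matches a direct step-up implementation", {
  set.seed(9)
  for (rep in 1:5) {
    p <- runif(50)
    manual <- {
      n <- length(p)
      o <- order(p)
      adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
      out <- numeric(n); out[o] <- adj; out
    }
    expect_equal(p.adjust(p, "BH"), manual)
  }
  # and the table's p_adj is BH over its own p
  d <- make_norm(seed = 10, shift_genes = 1)
  res <- hurdle_de(d$y, d$a, d$b)
  expect_equal(res$p_adj, p.adjust(res$p, "BH"))
  expect_true(all(res$p_adj >= res$p, na.rm = TRUE))
})

test_that("covariates are honoured and groups validated", {
  d <- make_norm(seed = 11)
  cov <- matrix(rnorm(nrow(d$y)), ncol = 1, dimnames = list(NULL, "ln_genes"))
  res <- hurdle_de(d$y, d$a, d$b, covariates = cov)
  expect_s3_class(res, "incite_de")
  expect_error(hurdle_de(d$y, d$a, d$a), class = "inciteseq_config_error")
  expect_error(hurdle_de(d$y, d$a & FALSE, d$b),
               class = "inciteseq_degenerate_error")
  g <- glance(res)
  expect_equal(g$n_cells_A, 60)
})

test_that("power: 2-fold shifted genes are recovered at high TPR", {
  d <- make_norm(n_per_group = 500, n_genes = 40, seed = 12,
                 shift_genes = 1:10, shift = log(2))
  res <- hurdle_de(d$y, d$a, d$b)
  tpr <- mean(res$is_deg[match(sprintf("g%d", 1:10), res$gene)])
  expect_gte(tpr, 0.8)
})
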