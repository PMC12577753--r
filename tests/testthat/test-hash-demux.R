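test_that("the default hashing design enumerates 12 samples", {
  samples <- enumerate_valid_samples(default_sample_design())
  expect_equal(nrow(samples), 12L)
  expect_equal(anyDuplicated(samples$sample_id), 0L)
  expect_setequal(unique(samples$condition), c("stimulated", "unstimulated"))
  expect_setequal(unique(samples$panel), c("panel1", "panel2"))
})

test_that("sample enumeration handles minimal and empty designs", {
  one <- sample_design(c(H1 = "stim"),
                       tibble::tibble(hashtag = "H2", culture = "A", panel = "p"),
                       panels = list(p = list(phospho = c("x", "y"), isotype = NULL)))
  expect_equal(nrow(enumerate_valid_samples(one)), 1L)

  none <- sample_design(c(H1 = "stim"),
                        tibble::tibble(hashtag = character(), culture = character(),
                                       panel = character()),
                        panels = list())
  expect_equal(nrow(enumerate_valid_samples(none)), 0L)
})

test_that("manual cutoffs override estimates verbatim and degenerate columns error", {
  m <- make_counts(matrix(c(rep(0, 5), rep(100, 5), rep(3, 10)), ncol = 2),
                   "hashtag", features = c("H1", "H2"))
  cuts <- estimate_hash_cutoffs(m, manual = c(H1 = 10, H2 = 7))
  expect_identical(unname(cuts[["H1"]]), 10)
  expect_identical(unname(cuts[["H2"]]), 7)
  expect_error(estimate_hash_cutoffs(m), class = "inciteseq_degenerate_error")
})

test_that("two-means cutoffs separate background from signal with <1% error", {
  set.seed(101)
  truth <- rep(c(FALSE, TRUE), each = 2000)
  counts <- c(rpois(2000, 2), rnbinom(2000, size = 10, mu = 200))
  m <- make_counts(matrix(counts, ncol = 1), "hashtag", features = "H1")
  cut <- estimate_hash_cutoffs(m)[["H1"]]
  called <- counts >= cut
  expect_lt(mean(called != truth), 0.01)
})

test_that("doublet and unassigned rules follow the positive-hash sets", {
  design <- default_sample_design()
  hashes <- c(paste0("Hashtag", 1:8))
  rows <- list(
    c("Hashtag1", "Hashtag4"),             # singlet: cultureB unstim panel1
    c("Hashtag1", "Hashtag2", "Hashtag3"), # both condition hashes -> doublet
    c("Hashtag3", "Hashtag7"),             # 2 identity hashes -> doublet (no condition hash would also be unassigned; rule is disjunctive)
    c("Hashtag2"),                         # no identity hash -> unassigned
    c("Hashtag5")                          # no condition hash -> unassigned
  )
  m <- matrix(0, length(rows), 8, dimnames = list(sprintf("c%d", seq_along(rows)), hashes))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 100
  cuts <- setNames(rep(10, 8), hashes)
  res <- classify_cells(make_counts(m, "hashtag"), cuts, design)
  expect_equal(res$status, c("singlet", "doublet", "doublet", "unassigned", "unassigned"))
  expect_equal(res$sample_id[[1]], "cultureB_unstimulated_panel1")
  expect_equal(res$condition[[1]], "unstimulated")
  # statuses partition the cells
  expect_equal(sum(table(res$status)), nrow(m))
})

test_that("classification is invariant to cell and hashtag order", {
  set.seed(5)
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 15, seed = 9))
  cuts <- estimate_hash_cutoffs(ds$hto)
  res <- classify_cells(ds$hto, cuts, ds$truth$config$design)

  perm_cells <- sample(nrow(ds$hto))
  perm_hash <- sample(ncol(ds$hto))
  shuffled <- cell_counts(as.matrix(ds$hto)[perm_cells, perm_hash], "hashtag")
  res2 <- classify_cells(shuffled, cuts, ds$truth$config$design)
  res2 <- res2[match(res$barcode, res2$barcode), ]
  expect_equal(res$status, res2$status)
  expect_equal(res$sample_id, res2$sample_id)
})

test_that("empty hashtag matrices classify to an empty result", {
  design <- default_sample_design()
  m <- make_counts(matrix(0L, 0, 8), "hashtag",
                   features = paste0("Hashtag", 1:8))
  res <- classify_cells(m, setNames(rep(5, 8), paste0("Hashtag", 1:8)), design)
  expect_equal(nrow(res), 0L)
})

test_that("hashtags missing from the design are a configuration error", {
  design <- default_sample_design()
  m <- make_counts(matrix(1, 2, 1), "hashtag", features = "HashtagX")
  expect_error(classify_cells(m, c(HashtagX = 1), design),
               class = "inciteseq_config_error")
})

test_that("demux recovers truth on synthetic data", {
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 100, seed = 21,
                                     doublet_rate = 0.08))
  cuts <- estimate_hash_cutoffs(ds$hto)
  res <- classify_cells(ds$hto, cuts, ds$truth$config$design)
  tr <- ds$truth$cells
  recall <- mean(res$status[tr$is_doublet] == "doublet")
  acc <- mean(res$sample_id[!tr$is_doublet & res$status == "singlet"] ==
                tr$sample_id[!tr$is_doublet & res$status == "singlet"])
  expect_gte(recall, 0.90)
  expect_gte(acc, 0.98)
})
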