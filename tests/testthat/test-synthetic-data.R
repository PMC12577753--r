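test_that("degenerate configurations behave predictably", {
  empty <- generate_dataset(tiny_config(n_cells_per_sample = 0))
  expect_equal(nrow(empty$rna), 0L)
  expect_equal(nrow(empty$adt), 0L)
  expect_equal(nrow(empty$hto), 0L)
  expect_equal(nrow(empty$truth$cells), 0L)

  nodoub <- generate_dataset(tiny_config(n_cells_per_sample = 20,
                                         doublet_rate = 0, seed = 5))
  expect_equal(sum(nodoub$truth$cells$is_doublet), 0L)
})

test_that("configuration validation rejects bad inputs", {
  expect_error(tiny_config(doublet_rate = 1.5), class = "inciteseq_config_error")
  expect_error(tiny_config(dispersion = 0), class = "inciteseq_config_error")
  progs <- default_gene_programs()
  progs$extra <- list(genes = "Il2", lfc = 1, rule = list(type = "contaminant"))
  expect_error(tiny_config(gene_programs = progs),
               class = "inciteseq_config_error")
})

test_that("doublet flags replay the documented Bernoulli draw", {
  cfg <- tiny_config(n_cells_per_sample = 100, doublet_rate = 0.1, seed = 77)
  ds <- generate_dataset(cfg)
  # oracle: the first draws after seeding are the doublet indicators
  set.seed(77)
  expected <- runif(1200) < 0.1
  expect_identical(ds$truth$cells$is_doublet, expected)
  expect_identical(sum(ds$truth$cells$is_doublet), sum(expected))
})

test_that("identical configurations generate bit-identical output", {
  a <- generate_dataset(tiny_config(n_cells_per_sample = 25, seed = 31))
  b <- generate_dataset(tiny_config(n_cells_per_sample = 25, seed = 31))
  expect_identical(as.matrix(a$rna), as.matrix(b$rna))
  expect_identical(as.matrix(a$adt), as.matrix(b$adt))
  expect_identical(as.matrix(a$hto), as.matrix(b$hto))
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("matrices share one barcode axis and hold non-negative integers", {
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 20, seed = 2))
  expect_identical(rownames(ds$rna), rownames(ds$adt))
  expect_identical(rownames(ds$rna), rownames(ds$hto))
  expect_identical(rownames(ds$rna), ds$truth$cells$barcode)
  for (m in list(ds$rna, ds$adt, ds$hto)) {
    expect_true(all(m@x >= 0))
    expect_true(all(m@x == trunc(m@x)))
  }
})

test_that("doublet profiles are sums of their recorded constituents", {
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 40, seed = 8,
                                     doublet_rate = 0.15),
                         keep_doublet_parents = TRUE)
  parents <- attr(ds$truth, "doublet_parents")
  expect_gt(length(parents$barcodes), 0)
  for (mod in c("rna", "adt", "hto")) {
    got <- as.matrix(ds[[mod]][parents$barcodes, , drop = FALSE])
    want <- as.matrix(parents$primary[[mod]]) + as.matrix(parents$partner[[mod]])
    expect_equal(unname(got), unname(want))
  }
})

test_that("truth positive fractions match the configured rates", {
  cfg <- tiny_config(n_cells_per_sample = 1000, n_genes = 300, seed = 19)
  ds <- generate_dataset(cfg)
  tf <- truth_positive_fractions(ds$truth)
  conf <- dplyr::rename(cfg$positive_fraction, target_id = "target")
  j <- dplyr::inner_join(tf, conf, by = c("culture", "condition", "target_id"))
  expect_equal(nrow(j), nrow(tf))
  # 99% binomial confidence band around the configured fraction
  z <- stats::qnorm(0.995)
  half <- z * sqrt(j$fraction.y * (1 - j$fraction.y) / j$n_cells)
  expect_true(all(abs(j$fraction.x - j$fraction.y) <= pmax(half, 0.005)))
})

test_that("stimulated cells detect about 3,000 genes under defaults", {
  ds <- generate_dataset(generator_config(n_cells_per_sample = 40, seed = 3))
  tr <- ds$truth$cells
  qc <- compute_qc_metrics(ds$rna)
  keep <- !tr$is_doublet & !tr$is_contaminant & tr$condition == "stimulated"
  expect_lt(abs(mean(qc$genes_detected[keep]) - 3026) / 3026, 0.10)
})

test_that("zero-noise flow tables equal truth fractions exactly", {
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 50, seed = 23))
  flow <- generate_flow_table(ds$truth, noise_sd = 0)
  tf <- truth_positive_fractions(ds$truth)
  j <- dplyr::inner_join(flow, tf, by = c("sample_id", "target_id"))
  expect_equal(j$percent_positive, 100 * j$fraction)

  empty <- generate_dataset(tiny_config(n_cells_per_sample = 0))
  expect_error(generate_flow_table(empty$truth), class = "inciteseq_config_error")
})

test_that("a known truth fraction of 0.864 prints as 86.4 percent", {
  cells <- tibble::tibble(
    barcode = sprintf("c%d", 1:1000), sample_id = "cultureA_stimulated_panel2",
    condition = "stimulated", culture = "cultureA", panel = "panel2",
    is_doublet = FALSE, sample_id2 = NA_character_, is_contaminant = FALSE,
    cluster = "stimulated",
    `pos_p-STAT3` = NA, `pos_p-p65` = NA,
    `pos_p-ERK1/2` = NA, `pos_p-FOS` = rep(c(TRUE, FALSE), c(864, 136)))
  truth <- structure(list(cells = cells, config = generator_config()),
                     class = "synthetic_truth")
  flow <- generate_flow_table(truth, noise_sd = 0)
  expect_equal(flow$percent_positive[flow$target_id == "p-FOS"], 86.4)
})

test_that("datasets round-trip through CellRanger-style directories", {
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 10, seed = 6))
  d <- withr::local_tempdir()
  write_dataset(ds, d)
  back <- read_counts_dir(file.path(d, "rna"), "gene")
  expect_identical(as.matrix(back), as.matrix(ds$rna))
  expect_true(file.exists(file.path(d, "truth.tsv")))
  expect_true(file.exists(file.path(d, "config.yaml")))
})
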