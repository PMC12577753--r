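mini_adt <- function(raw, barcodes) {
  # raw: matrix with columns pX, pY, iso
  make_counts(raw, "adt", cells = barcodes, features = colnames(raw))
}

test_that("isotype medians use the mean-of-middle convention per group", {
  design <- mini_design()
  bc <- sprintf("c%d", 1:5)
  raw <- cbind(pX = rep(0, 5), pY = rep(0, 5), iso = c(3, 4, 5, 3, 5))
  ann <- dplyr::bind_rows(
    mini_annotations(bc[1:3], "cultureA", "stimulated"),
    mini_annotations(bc[4:5], "cultureB", "stimulated"))
  med <- compute_isotype_medians(mini_adt(raw, bc), ann, design)
  expect_equal(med$isotype_median[med$culture == "cultureA"], 4)  # odd n
  expect_equal(med$isotype_median[med$culture == "cultureB"], 4)  # {3,5} -> 4
})

test_that("the default design yields one median per culture x condition", {
  ds <- generate_dataset(tiny_config(n_cells_per_sample = 40, seed = 4))
  cuts <- estimate_hash_cutoffs(ds$hto)
  ann <- classify_cells(ds$hto, cuts, ds$truth$config$design)
  ann$pass_qc <- TRUE; ann$contaminant <- FALSE
  med <- compute_isotype_medians(ds$adt, ann, ds$truth$config$design)
  expect_equal(nrow(med), 6L)
  # generated backgrounds put group medians in the 3-5 range
  expect_true(all(med$isotype_median >= 3 & med$isotype_median <= 5))
})

test_that("groups without isotype-bearing cells raise an error", {
  design <- mini_design()
  bc <- c("c1", "c2")
  raw <- cbind(pX = c(0, 0), pY = c(0, 0), iso = c(3, 4))
  ann <- mini_annotations(bc, "cultureA", "stimulated")
  # a group that exists only in a panel with no isotype
  ann2 <- mini_annotations("c3", "cultureB", "unstimulated")
  ann2$panel <- "panel2"
  design$panels$panel2 <- list(phospho = c("pX", "pY"), isotype = NULL)
  expect_error(
    compute_isotype_medians(mini_adt(raw, bc), dplyr::bind_rows(ann, ann2), design),
    class = "inciteseq_degenerate_error")
})

test_that("correction clips at zero and logs the remainder", {
  design <- mini_design()
  bc <- sprintf("c%d", 1:3)
  raw <- cbind(pX = c(6, 2, 0), pY = c(0, 0, 0), iso = c(4, 4, 4))
  ann <- mini_annotations(bc, "cultureA", "stimulated")
  med <- tibble::tibble(culture = "cultureA", condition = "stimulated",
                        isotype_median = c(4), n_cells = 3L)
  q <- correct_and_call(mini_adt(raw, bc), med, design, ann)
  px <- q[q$target == "pX", ]
  expect_equal(px$corrected, c(log(3), 0, 0))
  expect_equal(px$positive, c(TRUE, FALSE, FALSE))
  # with a zero median, a zero count stays negative
  med0 <- dplyr::mutate(med, isotype_median = 0)
  q0 <- correct_and_call(mini_adt(raw, bc), med0, design, ann)
  expect_false(q0$positive[q0$target == "pX" & q0$barcode == "c3"])
  # isotype channel itself is not emitted
  expect_setequal(unique(q$target), c("pX", "pY"))
})

test_that("positivity is algebraically raw > group median (brute force)", {
  design <- mini_design()
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    bc <- sprintf("c%d", seq_len(n))
    raw <- cbind(pX = rpois(n, 4), pY = rpois(n, 4), iso = rpois(n, 4))
    ann <- mini_annotations(bc, "cultureA", "stimulated")
    med <- compute_isotype_medians(mini_adt(raw, bc), ann, design)
    q <- correct_and_call(mini_adt(raw, bc), med, design, ann)
    m <- med$isotype_median[[1]]
    for (tg in c("pX", "pY")) {
      brute <- log1p(pmax(0, raw[, tg] - m)) > 0
      expect_equal(q$positive[q$target == tg], unname(brute))
      expect_equal(q$positive[q$target == tg], unname(raw[, tg] > m))
    }
  }
})

test_that("raising the isotype median never increases corrected levels", {
  design <- mini_design()
  bc <- sprintf("c%d", 1:20)
  set.seed(7)
  raw <- cbind(pX = rpois(20, 10), pY = rpois(20, 10), iso = rpois(20, 4))
  ann <- mini_annotations(bc, "cultureA", "stimulated")
  med_lo <- tibble::tibble(culture = "cultureA", condition = "stimulated",
                           isotype_median = 2, n_cells = 20L)
  med_hi <- dplyr::mutate(med_lo, isotype_median = 6)
  q_lo <- correct_and_call(mini_adt(raw, bc), med_lo, design, ann)
  q_hi <- correct_and_call(mini_adt(raw, bc), med_hi, design, ann)
  expect_true(all(q_hi$corrected <= q_lo$corrected))
})

test_that("phospho states map combinations to the three categories", {
  design <- default_sample_design()
  quant <- tibble::tibble(
    barcode = rep(c("c1", "c2", "c3"), each = 2),
    sample_id = "cultureA_stimulated_panel2",
    culture = "cultureA", condition = "stimulated", panel = "panel2",
    target = rep(c("p-ERK1/2", "p-FOS"), 3),
    raw = 0, corrected = 0,
    positive = c(TRUE, TRUE,  TRUE, FALSE,  FALSE, FALSE))
  st <- annotate_phospho_states(quant, design)
  st <- st[match(c("c1", "c2", "c3"), st$barcode), ]
  expect_equal(st$state, c("double", "single:p-ERK1/2", "unphosphorylated"))

  bad <- design
  bad$panels$panel2$phospho <- "p-ERK1/2"
  expect_error(annotate_phospho_states(quant, bad),
               class = "inciteseq_config_error")
})

test_that("per-sample summaries are direct fractions", {
  quant <- tibble::tibble(
    barcode = sprintf("c%d", 1:10), sample_id = "cultureA_stimulated_panel1",
    culture = "cultureA", condition = "stimulated", panel = "panel1",
    target = "pX", raw = 1, corrected = c(rep(1, 4), rep(0, 6)),
    positive = c(rep(TRUE, 4), rep(FALSE, 6)))
  s <- summarize_per_sample(quant)
  expect_equal(s$percent_positive, 40)
  expect_equal(s$n_cells, 10L)
  s2 <- summarize_per_sample(dplyr::mutate(quant, positive = TRUE))
  expect_equal(s2$percent_positive, 100)
  # invariant to cell order
  s3 <- summarize_per_sample(quant[sample(10), ])
  expect_equal(s, s3)
})
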