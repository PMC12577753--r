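# Shared fixture builders. Everything is generated in code at test time.

# a small dense count matrix wrapped as cell_counts
make_counts <- function(m, modality = "gene", cells = NULL, features = NULL) {
  if (is.null(rownames(m))) {
    rownames(m) <- cells %||% sprintf("c%02d", seq_len(nrow(m)))
  }
  if (is.null(colnames(m))) {
    colnames(m) <- features %||% sprintf("f%02d", seq_len(ncol(m)))
  }
  cell_counts(m, modality)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fast, small generator configuration (few genes, small samples)
tiny_config <- function(n_cells_per_sample = 30, n_genes = 300, seed = 1, ...) {
  generator_config(n_cells_per_sample = n_cells_per_sample, n_genes = n_genes,
                   seed = seed, ...)
}

# a single-panel design with two phospho targets and an isotype
mini_design <- function() {
  sample_design(
    condition_hashes = c(H1 = "unstimulated", H2 = "stimulated"),
    identity_hashes = tibble::tibble(hashtag = c("H3", "H4"),
                                     culture = c("cultureA", "cultureB"),
                                     panel = "panel1"),
    panels = list(panel1 = list(phospho = c("pX", "pY"), isotype = "iso"))
  )
}

# hand-built annotations for phospho tests: all QC-passing singlets
mini_annotations <- function(barcodes, culture, condition, panel = "panel1") {
  tibble::tibble(barcode = barcodes, status = "singlet",
                 sample_id = paste(culture, condition, panel, sep = "_"),
                 condition = condition, culture = culture, panel = panel,
                 pass_qc = TRUE, contaminant = FALSE)
}
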