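#' Validate and normalize a run configuration
#'
#' Accepts a YAML file path or a plain list, fills in every default
#' (generator, QC thresholds 500 genes / 500 counts / 0.1 mito, DE settings
#' with `min_pct` 0.01, default contrasts) and resolves cross-references.
#' Validation problems are aggregated and reported together rather than
#' one at a time.
#'
#' @param config Path to a YAML file, or a named list with any of:
#'   `mode` (`"synthetic"` or `"directories"`), `paths` (list `rna`,
#'   `adt`, `hto`; directories mode), `generator` (overrides for
#'   [generator_config()]), `qc` (overrides for [qc_thresholds()]), `de`
#'   (overrides for [de_settings()]), `contrasts` (list of
#'   `list(name, type, ...)` with type `condition`, `positivity` or
#'   `state`), `flow_table` (path, optional), `flow_noise_sd`,
#'   `output_dir`, `seed`.
#' @return A normalized `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("mode", "paths", "design", "generator", "qc", "de", "contrasts",
             "flow_table", "flow_noise_sd", "output_dir", "seed")
  errors <- character()
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, sprintf("unknown configuration key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  mode <- config$mode %||% "synthetic"
  if (!mode %in% c("synthetic", "directories")) {
    errors <- c(errors, sprintf("mode must be 'synthetic' or 'directories', got '%s'", mode))
  }
  design <- config$design %||% default_sample_design()
  if (mode == "directories") {
    for (mdl in c("rna", "adt", "hto")) {
      if (is.null(config$paths[[mdl]])) {
        errors <- c(errors, sprintf("directories mode requires paths$%s", mdl))
      }
    }
  }
  qc <- tryCatch(do.call(qc_thresholds, config$qc %||% list()),
                 error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
  de <- tryCatch(do.call(de_settings, config$de %||% list()),
                 error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })

  targets <- all_phospho_targets(design)
  conditions <- unique(unname(design$condition_hashes))
  contrasts <- config$contrasts %||% c(
    list(list(name = "stim_vs_unstim", type = "condition",
              group_a = "stimulated", group_b = "unstimulated")),
    lapply(targets, function(tg) {
      list(name = paste0(gsub("[^A-Za-z0-9]+", "", tg), "_pos_vs_neg"),
           type = "positivity", target = tg)
    })
  )
  for (ct in contrasts) {
    nm <- ct$name %||% "<unnamed>"
    if (is.null(ct$type) || !ct$type %in% c("condition", "positivity", "state")) {
      errors <- c(errors, sprintf("contrast '%s': unknown type '%s'", nm,
                                  ct$type %||% "NULL"))
      next
    }
    if (ct$type == "condition") {
      bad <- setdiff(c(ct$group_a, ct$group_b), conditions)
      if (length(bad)) {
        errors <- c(errors, sprintf("contrast '%s': unknown condition(s) %s",
                                    nm, paste(bad, collapse = ", ")))
      }
      if (identical(ct$group_a, ct$group_b)) {
        errors <- c(errors, sprintf("contrast '%s': group A equals group B", nm))
      }
    }
    if (ct$type == "positivity" && !(ct$target %||% "") %in% targets) {
      errors <- c(errors, sprintf("contrast '%s': target '%s' not declared in any panel",
                                  nm, ct$target %||% "NULL"))
    }
    if (ct$type == "state") {
      if (identical(ct$state_a, ct$state_b)) {
        errors <- c(errors, sprintf("contrast '%s': group A equals group B", nm))
      }
      if (is.null(ct$panel) || !(ct$panel %in% names(design$panels))) {
        errors <- c(errors, sprintf("contrast '%s': unknown panel '%s'",
                                    nm, ct$panel %||% "NULL"))
      }
    }
  }
  if (anyDuplicated(vapply(contrasts, function(ct) ct$name %||% "", character(1)))) {
    errors <- c(errors, "contrast names must be unique")
  }
  if (length(errors)) {
    abort(paste0("invalid run configuration:\n",
                 paste0("  - ", errors, collapse = "\n")),
          class = "inciteseq_config_error")
  }
  structure(list(
    mode = mode, paths = config$paths, design = design,
    generator = config$generator %||% list(), qc = qc, de = de,
    contrasts = contrasts, flow_table = config$flow_table,
    flow_noise_sd = config$flow_noise_sd %||% 2,
    output_dir = config$output_dir, seed = as.integer(config$seed %||% 1L)
  ), class = "run_config")
}

# named per-stage substream of the root seed (kept below 2^31)
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629)
}

#' Run the full analysis pipeline
#'
#' Stage order: synthesize-or-read counts, hashtag demultiplexing, QC
#' filtering, contaminant flagging, isotype-corrected phospho
#' quantification and state annotation, cluster-wise size-factor
#' normalization, hurdle differential expression per contrast, signed
#' gene-set intersection, and flow concordance. Every intermediate table
#' is written under `output_dir` together with a consolidated JSON report;
#' an identical configuration yields byte-identical artifacts.
#'
#' @param config A `run_config` (see [validate_config()]), a list, or a
#'   YAML path.
#' @return The run report (a list, also written as `report.json`),
#'   invisibly; its `$tables` element holds the in-memory results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$output_dir %||% tempfile("incite_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  on_fail <- function(stage, e) {
    writeLines(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    abort(sprintf("pipeline stage '%s': %s", stage, conditionMessage(e)),
          class = "inciteseq_pipeline_error", parent = e)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) on_fail(name, e))
  }

  ## -- inputs ---------------------------------------------------------------
  truth <- NULL
  if (config$mode == "synthetic") {
    ds <- stage("generate", {
      gen <- do.call(generator_config,
                     c(config$generator,
                       list(design = config$design,
                            seed = derive_seed(config$seed, "generate"))))
      generate_dataset(gen)
    })
    rna <- ds$rna; adt <- ds$adt; hto <- ds$hto; truth <- ds$truth
  } else {
    rna <- stage("read", read_counts_dir(config$paths$rna, "gene"))
    adt <- stage("read", read_counts_dir(config$paths$adt, "adt"))
    hto <- stage("read", read_counts_dir(config$paths$hto, "hashtag"))
  }

  ## -- demultiplex ----------------------------------------------------------
  demux <- stage("demux", {
    cutoffs <- estimate_hash_cutoffs(hto)
    classify_cells(hto, cutoffs, config$design)
  })

  ## -- QC + contaminants ----------------------------------------------------
  qc_metrics <- stage("qc", compute_qc_metrics(rna))
  pass <- stage("qc", apply_qc(qc_metrics, config$qc))
  contaminant <- stage("contaminant",
    flag_contaminants(rna, config$qc$contaminant_marker_genes,
                      config$qc$contaminant_score_cutoff))
  annotations <- dplyr::mutate(
    dplyr::left_join(demux, qc_metrics, by = "barcode"),
    pass_qc = pass, contaminant = contaminant)

  ## -- phospho quantification ----------------------------------------------
  medians <- stage("phospho", compute_isotype_medians(adt, annotations, config$design))
  quant <- stage("phospho", correct_and_call(adt, medians, config$design, annotations))
  states <- stage("phospho", annotate_phospho_states(quant, config$design))
  summary_tbl <- stage("phospho", summarize_per_sample(quant))
  annotations <- dplyr::left_join(annotations, states[c("barcode", "state")],
                                  by = "barcode")

  ## -- normalization ---------------------------------------------------------
  keep <- annotations$status == "singlet" & annotations$pass_qc &
    !annotations$contaminant
  kept <- annotations[keep, ]
  norm <- stage("normalize", {
    rna_k <- rna[kept$barcode, , drop = FALSE]
    labels <- paste(kept$sample_id, kept$state %||% "none", sep = "|")
    small <- names(which(table(labels) < 2))
    labels[labels %in% small] <- kept$sample_id[labels %in% small]
    small <- names(which(table(labels) < 2))
    # any leftover singleton joins the largest cluster
    labels[labels %in% small] <- names(which.max(table(labels)))
    sf <- compute_size_factors(cell_counts(rna_k, "gene"), labels)
    list(y = normalize_counts(rna_k, sf), size_factors = sf, labels = labels)
  })

  ## -- differential expression ----------------------------------------------
  de_tables <- stage("de", {
    cov <- matrix(kept$ln_genes, ncol = 1, dimnames = list(NULL, "ln_genes"))
    res <- list()
    for (ct in config$contrasts) {
      groups <- contrast_groups(ct, kept, quant, states)
      if (is.null(groups)) next
      res[[ct$name]] <- hurdle_de(norm$y, groups$a, groups$b,
                                  covariates = cov, settings = config$de)
    }
    res
  })

  ## -- gene-set intersections -----------------------------------------------
  partition <- stage("intersect", {
    if (length(de_tables)) {
      intersect_sets(build_signed_sets(de_tables, alpha = config$de$alpha))
    } else NULL
  })

  ## -- concordance -----------------------------------------------------------
  flow <- NULL
  if (!is.null(config$flow_table)) {
    flow <- stage("concordance", read_flow_table(config$flow_table))
  } else if (!is.null(truth)) {
    flow <- stage("concordance",
      generate_flow_table(truth, noise_sd = config$flow_noise_sd,
                          seed = derive_seed(config$seed, "flow")))
  }
  concord <- if (!is.null(flow)) {
    stage("concordance", suppressWarnings(compare_modalities(summary_tbl, flow)))
  } else NULL

  ## -- artifacts + report ----------------------------------------------------
  readr::write_tsv(annotations, file.path(out_dir, "cell_annotations.tsv"))
  readr::write_tsv(medians, file.path(out_dir, "isotype_medians.tsv"))
  readr::write_tsv(quant, file.path(out_dir, "phospho_quant.tsv"))
  readr::write_tsv(summary_tbl, file.path(out_dir, "sample_summary.tsv"))
  for (nm in names(de_tables)) {
    readr::write_tsv(tidy(de_tables[[nm]]),
                     file.path(out_dir, paste0("de_", nm, ".tsv")))
  }
  if (!is.null(partition)) {
    flat <- dplyr::mutate(partition,
                          members = vapply(.data$members, paste, "", collapse = ","))
    readr::write_tsv(flat, file.path(out_dir, "gene_set_partition.tsv"))
  }
  if (!is.null(concord)) {
    readr::write_tsv(tidy(concord), file.path(out_dir, "concordance.tsv"))
  }
  if (!is.null(truth)) {
    readr::write_tsv(truth$cells, file.path(out_dir, "truth.tsv"))
  }

  n_cells <- nrow(rna)
  tallies <- list(
    cells_in = n_cells,
    demux = as.list(table(factor(annotations$status,
                                 c("singlet", "doublet", "unassigned")))),
    qc_fail = sum(annotations$status == "singlet" & !annotations$pass_qc),
    contaminants = sum(annotations$status == "singlet" &
                         annotations$pass_qc & annotations$contaminant),
    cells_analysed = nrow(kept)
  )
  artifacts <- sort(setdiff(list.files(out_dir), c("report.json", "FAILED")))
  report <- list(
    package = "inciteseq",
    version = as.character(utils::packageVersion("inciteseq")),
    seed = config$seed,
    mode = config$mode,
    parameters = list(
      qc = unclass(config$qc), de = unclass(config$de),
      flow_noise_sd = config$flow_noise_sd,
      n_contrasts = length(config$contrasts)
    ),
    tallies = tallies,
    isotype_medians = as.list(setNames(medians$isotype_median,
                                       paste(medians$culture, medians$condition,
                                             sep = "_"))),
    de = lapply(de_tables, function(tb) as.list(glance(tb))),
    n_signatures = if (!is.null(partition)) nrow(partition) else 0L,
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts)))
  )
  names(report$checksums) <- artifacts
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$tables <- list(annotations = annotations, medians = medians,
                        quant = quant, states = states, summary = summary_tbl,
                        de = de_tables, partition = partition,
                        concordance = concord, flow = flow, truth = truth,
                        size_factors = norm$size_factors)
  report$output_dir <- out_dir
  invisible(report)
}

# resolve a contrast definition to disjoint cell masks over `kept`
contrast_groups <- function(ct, kept, quant, states) {
  if (ct$type == "condition") {
    a <- kept$condition == ct$group_a
    b <- kept$condition == ct$group_b
  } else if (ct$type == "positivity") {
    q <- quant[quant$target == ct$target, ]
    pos_bc <- q$barcode[q$positive]
    neg_bc <- q$barcode[!q$positive]
    a <- kept$barcode %in% pos_bc
    b <- kept$barcode %in% neg_bc
  } else {  # state
    st <- states[states$panel == ct$panel, ]
    a <- kept$barcode %in% st$barcode[st$state == ct$state_a]
    b <- kept$barcode %in% st$barcode[st$state == ct$state_b]
  }
  if (sum(a) < 20 || sum(b) < 20) {
    warn(sprintf("contrast '%s' skipped: fewer than 20 cells in a group", ct$name))
    return(NULL)
  }
  list(a = a, b = b)
}
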