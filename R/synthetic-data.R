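#' Default phospho-positive fractions
#'
#' Per (culture, condition, target) truth fractions used by the generator.
#' The p-FOS pair (5.42% unstimulated, 86.4% stimulated) reflects the
#' flow-cytometry shift the experiment exhibits; p-ERK1/2 rises strongly
#' with stimulation, p-p65 moderately, and p-STAT3 stays high in both
#' conditions (it is driven by IL-6 in the culture medium rather than by
#' the secondary stimulation). Cultures A/B/C scale the base fraction by
#' 0.92/1.00/1.08 to emulate biological replicate variation.
#'
#' @param design A [sample_design()].
#' @return A tibble: `culture`, `condition`, `target`, `fraction`.
#' @export
default_positive_fractions <- function(design = default_sample_design()) {
  base <- tibble::tribble(
    ~target,     ~unstimulated, ~stimulated,
    "p-STAT3",   0.70,          0.75,
    "p-p65",     0.25,          0.40,
    "p-ERK1/2",  0.10,          0.75,
    "p-FOS",     0.0542,        0.864
  )
  base <- tidyr::pivot_longer(base, -"target", names_to = "condition",
                              values_to = "fraction")
  cultures <- unique(design$identity_hashes$culture)
  mult <- setNames(seq(0.92, 1.08, length.out = length(cultures)), sort(cultures))
  out <- tidyr::crossing(culture = names(mult), base)
  dplyr::transmute(out, .data$culture, .data$condition, .data$target,
                   fraction = pmin(1, pmax(0, .data$fraction * mult[.data$culture])))
}

#' Default phospho-state-coupled gene programs
#'
#' Each program is a gene list with a log-fold effect applied when its rule
#' is active in a cell: `condition` rules key on the cell's stimulation
#' state, `positive` rules on truth positivity for one target,
#' `double_positive` on joint positivity for the cell's panel pair, and
#' `contaminant` on contaminant identity. Contaminant cells activate only
#' contaminant-rule programs.
#'
#' @return Named list of programs (`genes`, `lfc`, `rule`).
#' @export
default_gene_programs <- function() {
  list(
    activation = list(
      genes = c("Il2", "Il17a", "Il17f", "Tnf", "Cd69", "Cd40lg", "Tnfrsf4"),
      lfc = 1.5, rule = list(type = "condition", value = "stimulated")),
    hyperactivation = list(
      genes = c("Il21", "Mir155hg", "Jak2", "Nfkb1", "Rela"),
      lfc = 1.2, rule = list(type = "double_positive")),
    resting = list(
      genes = c("Tcf7", "Ccr7", "Sell", "Lef1"),
      lfc = 1.2, rule = list(type = "condition", value = "unstimulated")),
    proliferation = list(
      genes = c("Mki67", "Top2a", "Cdk1", "Cdk4", "Cenpf"),
      lfc = 1.0, rule = list(type = "positive", value = "p-STAT3")),
    lipid_metabolism = list(
      genes = c("Scd2", "Fasn", "Dgat1", "Fabp5", "Acot7"),
      lfc = 1.0, rule = list(type = "positive", value = "p-STAT3")),
    contaminant_marker = list(
      genes = c("Cd79a", "Cd79b", "Ms4a1"),
      lfc = 4.0, rule = list(type = "contaminant"))
  )
}

mito_gene_ids <- function(prefix = "mt-") {
  paste0(prefix, c("Nd1", "Nd2", "Co1", "Co2", "Atp8", "Atp6", "Co3",
                   "Nd3", "Nd4l", "Nd4", "Nd5", "Nd6", "Cytb"))
}

#' Generator configuration
#'
#' Defaults emulate the study conditions of a stimulated-vs-control Th17
#' hashing experiment: 12 samples (2 conditions x 3 cultures x 2 antibody
#' panels) in one well; per-cell transcript totals log-normal with mean
#' 6,644 (SD 3,998) stimulated and 6,103 (SD 3,837) unstimulated; gene
#' baseline abundances Gamma-heterogeneous over `n_genes` genes, calibrated
#' so stimulated cells detect about 3,026 genes; isotype-control background
#' with per-group medians in the 3-5 range; condition-dependent
#' phospho-positive fractions (5.42% to 86.4% for p-FOS); cross-sample
#' doublets at 8%; a 7% contaminant (B-cell-like) population; and
#' mitochondrial fractions Beta-distributed around 0.04.
#'
#' @param n_cells_per_sample Cells generated per sample.
#' @param design A [sample_design()].
#' @param n_genes Total genes, mitochondrial genes included.
#' @param gene_weight_shape Gamma shape of baseline gene abundances
#'   (smaller = more skewed).
#' @param dispersion Negative-binomial size for gene counts.
#' @param mean_counts_per_cell,sd_counts_per_cell Named per-condition
#'   log-normal moments of per-cell transcript totals.
#' @param gene_programs See [default_gene_programs()].
#' @param isotype_background_mean NB mean of the isotype-control channel.
#' @param phospho_background_mean NB mean of nonspecific phospho-antibody
#'   background (below the isotype median by design: the isotype clone is
#'   selected for high nonspecific binding).
#' @param phospho_signal_mean NB mean of the specific signal added for
#'   truth-positive cells.
#' @param adt_dispersion NB size for ADT channels.
#' @param positive_fraction Tibble (culture, condition, target, fraction);
#'   see [default_positive_fractions()].
#' @param doublet_rate Fraction of cells that are cross-sample doublets.
#' @param hash_signal_mean,hash_dispersion NB parameters of a cell's own
#'   hashtags (signal mean is 100x the ambient rate, guaranteeing cutoff
#'   separability at defaults).
#' @param ambient_hash_rate Poisson rate of ambient counts in every hashtag.
#' @param adt_ambient_rate Poisson rate of ADT channels not stained in the
#'   cell's panel.
#' @param contaminant_fraction Fraction of contaminant cells.
#' @param mito_fraction_mean,mito_concentration Beta moments of the
#'   per-cell mitochondrial count share.
#' @param mito_prefix Feature-id prefix of mitochondrial genes.
#' @param seed Integer seed; identical configurations generate bit-identical
#'   output.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cells_per_sample = 500L,
                             design = default_sample_design(),
                             n_genes = 6300L,
                             gene_weight_shape = 3,
                             dispersion = 2,
                             mean_counts_per_cell = c(unstimulated = 6103, stimulated = 6644),
                             sd_counts_per_cell = c(unstimulated = 3837, stimulated = 3998),
                             gene_programs = default_gene_programs(),
                             isotype_background_mean = 4,
                             phospho_background_mean = 1,
                             phospho_signal_mean = 60,
                             adt_dispersion = 8,
                             positive_fraction = default_positive_fractions(design),
                             doublet_rate = 0.08,
                             hash_signal_mean = 200,
                             hash_dispersion = 10,
                             ambient_hash_rate = 2,
                             adt_ambient_rate = 0.1,
                             contaminant_fraction = 0.07,
                             mito_fraction_mean = 0.04,
                             mito_concentration = 50,
                             mito_prefix = "mt-",
                             seed = 1L) {
  cfg <- list(n_cells_per_sample = as.integer(n_cells_per_sample),
              design = design, n_genes = as.integer(n_genes),
              gene_weight_shape = gene_weight_shape, dispersion = dispersion,
              mean_counts_per_cell = mean_counts_per_cell,
              sd_counts_per_cell = sd_counts_per_cell,
              gene_programs = gene_programs,
              isotype_background_mean = isotype_background_mean,
              phospho_background_mean = phospho_background_mean,
              phospho_signal_mean = phospho_signal_mean,
              adt_dispersion = adt_dispersion,
              positive_fraction = tibble::as_tibble(positive_fraction),
              doublet_rate = doublet_rate,
              hash_signal_mean = hash_signal_mean,
              hash_dispersion = hash_dispersion,
              ambient_hash_rate = ambient_hash_rate,
              adt_ambient_rate = adt_ambient_rate,
              contaminant_fraction = contaminant_fraction,
              mito_fraction_mean = mito_fraction_mean,
              mito_concentration = mito_concentration,
              mito_prefix = mito_prefix, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  fracs <- c(cfg$doublet_rate, cfg$contaminant_fraction, cfg$mito_fraction_mean,
             cfg$positive_fraction$fraction)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all fractions must lie in [0, 1]", class = "inciteseq_config_error")
  }
  pos <- c(cfg$dispersion, cfg$mean_counts_per_cell, cfg$sd_counts_per_cell,
           cfg$isotype_background_mean, cfg$phospho_background_mean,
           cfg$phospho_signal_mean, cfg$adt_dispersion, cfg$hash_signal_mean,
           cfg$hash_dispersion, cfg$ambient_hash_rate, cfg$gene_weight_shape,
           cfg$mito_concentration)
  if (any(pos <= 0)) {
    abort("all means and dispersions must be strictly positive",
          class = "inciteseq_config_error")
  }
  if (cfg$n_cells_per_sample < 0) {
    abort("n_cells_per_sample must be non-negative", class = "inciteseq_config_error")
  }
  if (anyDuplicated(names(cfg$gene_programs))) {
    abort("gene program names must be unique", class = "inciteseq_config_error")
  }
  prog_genes <- unlist(lapply(cfg$gene_programs, `[[`, "genes"))
  if (anyDuplicated(prog_genes)) {
    dup <- unique(prog_genes[duplicated(prog_genes)])
    abort(sprintf("gene(s) shared between programs with independent effects: %s",
                  paste(dup, collapse = ", ")),
          class = "inciteseq_config_error")
  }
  if (!nrow(enumerate_valid_samples(cfg$design))) {
    abort("design enumerates zero samples", class = "inciteseq_config_error")
  }
  invisible(cfg)
}

all_phospho_targets <- function(design) {
  unique(unlist(lapply(design$panels, `[[`, "phospho")))
}

#' Generate a multimodal synthetic dataset with ground truth
#'
#' Draws RNA, ADT and hashtag count matrices over one shared cell-barcode
#' axis, plus a per-cell truth table. The random draw order under
#' `set.seed(config$seed)` is fixed and documented: (1) per-cell doublet
#' indicators `runif(n_total) < doublet_rate`; (2) doublet partner samples;
#' (3) per-profile contaminant indicators; (4) baseline gene weights;
#' (5) phospho truth; (6) per-profile totals, mito shares, RNA, ADT and
#' hashtag counts. Doublets are element-wise sums of two independently
#' drawn singlet profiles from distinct samples.
#'
#' @param config A [generator_config()].
#' @param keep_doublet_parents If `TRUE`, attach the two constituent
#'   profiles of every doublet (list of matrices) as attribute
#'   `"doublet_parents"` on the truth object, for conservation checks.
#' @return A list: `rna`, `adt`, `hto` ([cell_counts()] matrices sharing
#'   one barcode axis) and `truth` (a `synthetic_truth` object: `$cells`
#'   tibble + `$config`).
#' @export
generate_dataset <- function(config = generator_config(),
                             keep_doublet_parents = FALSE) {
  validate_generator_config(config)
  design <- config$design
  samples <- enumerate_valid_samples(design)
  n_s <- nrow(samples)
  n_total <- config$n_cells_per_sample * n_s
  targets <- all_phospho_targets(design)
  iso_abs <- unique(unlist(lapply(design$panels, `[[`, "isotype")))
  adt_features <- c(targets, iso_abs)
  hash_features <- c(names(design$condition_hashes), design$identity_hashes$hashtag)
  feat <- generator_features(config)

  if (n_total == 0L) {
    empty <- function(f, mod) cell_counts(
      Matrix::Matrix(0L, 0, length(f), sparse = TRUE,
                     dimnames = list(character(), f)), mod)
    truth <- structure(list(cells = empty_truth_cells(targets), config = config),
                       class = "synthetic_truth")
    return(list(rna = empty(feat$ids, "gene"), adt = empty(adt_features, "adt"),
                hto = empty(hash_features, "hashtag"), truth = truth))
  }

  set.seed(config$seed)
  ## (1) doublet indicators
  is_doublet <- runif(n_total) < config$doublet_rate
  n_doub <- sum(is_doublet)
  ## (2) partner samples (uniform over the other samples)
  sample1 <- rep(seq_len(n_s), each = config$n_cells_per_sample)
  sample2 <- rep(NA_integer_, n_total)
  if (n_doub > 0 && n_s > 1) {
    shift <- sample.int(n_s - 1L, n_doub, replace = TRUE)
    sample2[is_doublet] <- (sample1[is_doublet] - 1L + shift) %% n_s + 1L
  } else if (n_doub > 0) {
    abort("doublet_rate > 0 requires at least two samples",
          class = "inciteseq_config_error")
  }

  ## profiles: primaries first, then doublet partners
  prof_sample <- c(sample1, sample2[is_doublet])
  n_prof <- length(prof_sample)
  prof <- samples[prof_sample, ]

  ## (3) contaminant indicators
  is_contam <- runif(n_prof) < config$contaminant_fraction

  ## (4) baseline gene weights
  w <- rgamma(feat$n_nonmito, shape = config$gene_weight_shape)
  w <- w / sum(w)

  ## (5) phospho truth per profile and target (NA outside the panel)
  pos <- matrix(NA, n_prof, length(targets), dimnames = list(NULL, targets))
  pf <- config$positive_fraction
  for (tg in targets) {
    panel_of <- names(design$panels)[vapply(design$panels,
                                            function(p) tg %in% p$phospho, logical(1))]
    in_panel <- prof$panel %in% panel_of
    frac <- dplyr::left_join(
      prof[in_panel, c("culture", "condition")],
      pf[pf$target == tg, c("culture", "condition", "fraction")],
      by = c("culture", "condition"))$fraction
    if (anyNA(frac)) {
      abort(sprintf("positive_fraction missing entries for target '%s'", tg),
            class = "inciteseq_config_error")
    }
    draw <- runif(sum(in_panel)) < frac
    pos[in_panel, tg] <- draw & !is_contam[in_panel]
  }

  ## (6) per-profile totals and mito shares
  mcond <- config$mean_counts_per_cell[prof$condition]
  scond <- config$sd_counts_per_cell[prof$condition]
  sdlog <- sqrt(log(1 + (scond / mcond)^2))
  meanlog <- log(mcond) - sdlog^2 / 2
  totals <- rlnorm(n_prof, meanlog, sdlog)
  a <- config$mito_fraction_mean * config$mito_concentration
  b <- (1 - config$mito_fraction_mean) * config$mito_concentration
  mito_share <- rbeta(n_prof, a, b)

  rna <- draw_rna_profiles(config, feat, w, prof, pos, is_contam, totals, mito_share)
  adt <- draw_adt_profiles(config, design, targets, iso_abs, prof, pos, is_contam)
  hto <- draw_hto_profiles(config, design, hash_features, prof)

  ## combine doublets: cell i = primary i (+ partner profile)
  parent_idx <- which(is_doublet)
  partner_rows <- n_total + seq_len(n_doub)
  expand <- if (n_doub > 0) {
    Matrix::sparseMatrix(i = parent_idx, j = seq_len(n_doub), x = 1,
                         dims = c(n_total, n_doub))
  } else NULL
  combine <- function(m) {
    out <- m[seq_len(n_total), , drop = FALSE]
    if (n_doub > 0) {
      out <- out + expand %*% m[partner_rows, , drop = FALSE]
    }
    methods::as(out, "CsparseMatrix")
  }
  barcodes <- sprintf("cell_%06d", seq_len(n_total))
  rna_m <- combine(rna); rownames(rna_m) <- barcodes
  adt_m <- combine(adt); rownames(adt_m) <- barcodes
  hto_m <- combine(hto); rownames(hto_m) <- barcodes

  cells <- tibble::tibble(
    barcode = barcodes,
    sample_id = samples$sample_id[sample1],
    condition = samples$condition[sample1],
    culture = samples$culture[sample1],
    panel = samples$panel[sample1],
    is_doublet = is_doublet,
    sample_id2 = ifelse(is_doublet, samples$sample_id[sample2], NA_character_),
    is_contaminant = is_contam[seq_len(n_total)],
    cluster = ifelse(is_contam[seq_len(n_total)], "contaminant",
                     samples$condition[sample1])
  )
  pos_primary <- tibble::as_tibble(pos[seq_len(n_total), , drop = FALSE])
  names(pos_primary) <- paste0("pos_", targets)
  cells <- dplyr::bind_cols(cells, pos_primary)

  truth <- structure(list(cells = cells, config = config),
                     class = "synthetic_truth")
  if (keep_doublet_parents && n_doub > 0) {
    attr(truth, "doublet_parents") <- list(
      barcodes = barcodes[parent_idx],
      primary = list(rna = rna[parent_idx, , drop = FALSE],
                     adt = adt[parent_idx, , drop = FALSE],
                     hto = hto[parent_idx, , drop = FALSE]),
      partner = list(rna = rna[partner_rows, , drop = FALSE],
                     adt = adt[partner_rows, , drop = FALSE],
                     hto = hto[partner_rows, , drop = FALSE]))
  }
  list(rna = cell_counts(rna_m, "gene"), adt = cell_counts(adt_m, "adt"),
       hto = cell_counts(hto_m, "hashtag"), truth = truth)
}

empty_truth_cells <- function(targets) {
  cells <- tibble::tibble(barcode = character(), sample_id = character(),
                          condition = character(), culture = character(),
                          panel = character(), is_doublet = logical(),
                          sample_id2 = character(), is_contaminant = logical(),
                          cluster = character())
  for (tg in targets) cells[[paste0("pos_", tg)]] <- logical()
  cells
}

generator_features <- function(config) {
  prog_genes <- unique(unlist(lapply(config$gene_programs, `[[`, "genes")))
  mito <- mito_gene_ids(config$mito_prefix)
  n_filler <- config$n_genes - length(mito) - length(prog_genes)
  if (n_filler < 0) {
    abort("n_genes too small to hold the program and mitochondrial genes",
          class = "inciteseq_config_error")
  }
  nonmito <- c(prog_genes, sprintf("Gene%05d", seq_len(n_filler)))
  list(ids = c(nonmito, mito), nonmito = nonmito, mito = mito,
       n_nonmito = length(nonmito))
}

program_active <- function(prog, prof, pos, is_contam) {
  rule <- prog$rule
  act <- switch(rule$type,
    condition = prof$condition == rule$value,
    positive = !is.na(pos[, rule$value]) & pos[, rule$value],
    double_positive = {
      both <- rep(FALSE, nrow(prof))
      for (i in seq_len(nrow(prof))) {
        tg <- colnames(pos)[!is.na(pos[i, ])]
        both[i] <- length(tg) >= 2 && all(pos[i, tg])
      }
      both
    },
    contaminant = is_contam,
    abort(sprintf("unknown program rule type '%s'", rule$type),
          class = "inciteseq_config_error")
  )
  if (rule$type != "contaminant") act <- act & !is_contam
  act
}

draw_rna_profiles <- function(config, feat, w, prof, pos, is_contam,
                              totals, mito_share, chunk = 1000L) {
  n_prof <- nrow(prof)
  active <- lapply(config$gene_programs, program_active,
                   prof = prof, pos = pos, is_contam = is_contam)
  gene_idx <- lapply(config$gene_programs,
                     function(p) match(p$genes, feat$nonmito))
  n_mito <- length(feat$mito)
  blocks <- vector("list", ceiling(n_prof / chunk))
  for (bi in seq_along(blocks)) {
    rows <- seq((bi - 1L) * chunk + 1L, min(bi * chunk, n_prof))
    B <- length(rows)
    W <- matrix(w, nrow = B, ncol = feat$n_nonmito, byrow = TRUE)
    for (pi in seq_along(config$gene_programs)) {
      on <- active[[pi]][rows]
      if (any(on)) {
        W[on, gene_idx[[pi]]] <- W[on, gene_idx[[pi]], drop = FALSE] *
          exp(config$gene_programs[[pi]]$lfc)
      }
    }
    W <- W / rowSums(W)
    mu <- W * (totals[rows] * (1 - mito_share[rows]))
    cnt <- matrix(rnbinom(length(mu), size = config$dispersion, mu = as.vector(mu)),
                  nrow = B)
    mu_mito <- matrix(rep(totals[rows] * mito_share[rows] / n_mito, n_mito),
                      nrow = B)
    cnt_mito <- matrix(rnbinom(length(mu_mito), size = config$dispersion,
                               mu = as.vector(mu_mito)), nrow = B)
    blocks[[bi]] <- methods::as(Matrix::Matrix(cbind(cnt, cnt_mito), sparse = TRUE),
                                "CsparseMatrix")
  }
  m <- do.call(rbind, blocks)
  colnames(m) <- feat$ids
  m
}

draw_adt_profiles <- function(config, design, targets, iso_abs, prof, pos, is_contam) {
  n_prof <- nrow(prof)
  feats <- c(targets, iso_abs)
  m <- matrix(0, n_prof, length(feats), dimnames = list(NULL, feats))
  for (f in feats) {
    in_panel <- vapply(prof$panel, function(p) {
      pd <- design$panels[[p]]
      f %in% pd$phospho || identical(pd$isotype, f)
    }, logical(1))
    cnt <- rpois(n_prof, config$adt_ambient_rate)   # ambient everywhere
    if (f %in% iso_abs) {
      cnt[in_panel] <- cnt[in_panel] +
        rnbinom(sum(in_panel), size = config$adt_dispersion,
                mu = config$isotype_background_mean)
    } else {
      cnt[in_panel] <- cnt[in_panel] +
        rnbinom(sum(in_panel), size = config$adt_dispersion,
                mu = config$phospho_background_mean)
      hot <- in_panel & !is.na(pos[, f]) & pos[, f]
      cnt[hot] <- cnt[hot] + rnbinom(sum(hot), size = config$adt_dispersion,
                                     mu = config$phospho_signal_mean)
    }
    m[, f] <- cnt
  }
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

draw_hto_profiles <- function(config, design, hash_features, prof) {
  n_prof <- nrow(prof)
  cond_hash <- names(design$condition_hashes)[
    match(prof$condition, design$condition_hashes)]
  id_key <- paste(prof$culture, prof$panel)
  id_tab <- design$identity_hashes
  id_hash <- id_tab$hashtag[match(id_key, paste(id_tab$culture, id_tab$panel))]
  m <- matrix(rpois(n_prof * length(hash_features), config$ambient_hash_rate),
              n_prof, length(hash_features),
              dimnames = list(NULL, hash_features))
  for (h in hash_features) {
    own <- cond_hash == h | id_hash == h
    if (any(own)) {
      m[own, h] <- m[own, h] + rnbinom(sum(own), size = config$hash_dispersion,
                                       mu = config$hash_signal_mean)
    }
  }
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d cells (%d doublets, %d contaminants), seed %d\n",
              nrow(x$cells), sum(x$cells$is_doublet),
              sum(x$cells$is_contaminant), x$config$seed))
  invisible(x)
}

#' Truth positive fractions per sample and target
#'
#' Fractions among non-doublet, non-contaminant cells — the population the
#' pipeline's per-sample summaries estimate.
#'
#' @param truth A `synthetic_truth` object.
#' @return A tibble: `sample_id` (`<culture>_<condition>`), `culture`,
#'   `condition`, `target_id`, `fraction`, `n_cells`.
#' @export
truth_positive_fractions <- function(truth) {
  cells <- dplyr::filter(truth$cells, !.data$is_doublet, !.data$is_contaminant)
  targets <- all_phospho_targets(truth$config$design)
  long <- tidyr::pivot_longer(
    cells[c("culture", "condition", paste0("pos_", targets))],
    dplyr::all_of(paste0("pos_", targets)),
    names_to = "target_id", values_to = "positive", names_prefix = "pos_")
  long <- dplyr::filter(long, !is.na(.data$positive))
  dplyr::summarise(
    dplyr::group_by(long, .data$culture, .data$condition, .data$target_id),
    fraction = mean(.data$positive), n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(sample_id = paste(.data$culture, .data$condition, sep = "_"),
                  .before = 1L)
}

#' Truth-derived sample summary
#'
#' The sequencing-side summary implied directly by the ground truth (no
#' measurement noise): percent positivity is the truth fraction x 100 and
#' the magnitude is `fraction x ln(1 + phospho_signal_mean)`. Useful as the
#' exactly-matched counterpart of a zero-noise flow table.
#'
#' @param truth A `synthetic_truth` object.
#' @return A tibble shaped like [summarize_per_sample()] output.
#' @export
truth_sample_summary <- function(truth) {
  tf <- truth_positive_fractions(truth)
  sig <- log1p(truth$config$phospho_signal_mean)
  dplyr::transmute(tf, .data$sample_id, .data$culture, .data$condition,
                   .data$target_id,
                   percent_positive = 100 * .data$fraction,
                   mean_corrected = .data$fraction * sig,
                   n_cells = .data$n_cells)
}

#' Generate a paired flow-cytometry summary table
#'
#' One row per (sample, target): percent positive is the truth fraction x
#' 100 plus Gaussian noise (clipped to \[0, 100\]); MFI is a linear (hence
#' monotone) transform of the mean true signal, `50 + 10 x fraction x
#' ln(1 + phospho_signal_mean)`, plus noise.
#'
#' @param truth A `synthetic_truth` object with at least one cell.
#' @param noise_sd Gaussian noise SD (percent-positivity points; the MFI
#'   noise uses the same SD on the MFI scale).
#' @param seed Seed for the noise draws.
#' @return A validated flow summary tibble (`sample_id`, `target_id`,
#'   `percent_positive`, `mfi`).
#' @export
generate_flow_table <- function(truth, noise_sd = 0, seed = 1L) {
  if (!nrow(truth$cells)) {
    abort("cannot build a flow table from empty truth",
          class = "inciteseq_config_error")
  }
  stopifnot(noise_sd >= 0)
  tf <- truth_positive_fractions(truth)
  sig <- log1p(truth$config$phospho_signal_mean)
  set.seed(seed)
  out <- dplyr::transmute(tf, .data$sample_id, .data$target_id,
    percent_positive = pmin(100, pmax(0, 100 * .data$fraction +
                                        rnorm(dplyr::n(), 0, noise_sd))),
    mfi = 50 + 10 * .data$fraction * sig + rnorm(dplyr::n(), 0, noise_sd))
  validate_flow_table(out)
}

#' Write a generated dataset as CellRanger-style directories
#'
#' Writes one count directory per modality (`rna/`, `adt/`, `hto/`), the
#' truth table as TSV and the configuration echo as YAML.
#'
#' @param dataset The list returned by [generate_dataset()].
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_counts_dir(dataset$rna, file.path(path, "rna"))
  write_counts_dir(dataset$adt, file.path(path, "adt"))
  write_counts_dir(dataset$hto, file.path(path, "hto"))
  readr::write_tsv(dataset$truth$cells, file.path(path, "truth.tsv"))
  cfg <- dataset$truth$config
  echo <- cfg[setdiff(names(cfg), c("design", "gene_programs", "positive_fraction"))]
  echo$positive_fraction <- as.data.frame(cfg$positive_fraction)
  yaml::write_yaml(echo, file.path(path, "config.yaml"))
  invisible(path)
}
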