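#' Antibody-oligo specification
#'
#' Describes an antibody-conjugated capture oligo as an ordered list of
#' segments (PCR handle, random spacers, sample/antibody barcode, bead
#' capture sequence) plus 3' modification flags.
#'
#' @param segments Data frame with columns `role` (one of `pcr_handle`,
#'   `spacer`, `barcode`, `capture`), `length` (declared bases) and
#'   optionally `sequence` (may be `NA` for random segments).
#' @param phosphorothioate_3p Number of phosphorothioated bonds at the 3'
#'   end.
#' @param dideoxy_3p Whether the 3' terminus is a dideoxy base (blocks
#'   polymerase extension).
#' @return An `oligo_spec` object.
#' @export
oligo_spec <- function(segments, phosphorothioate_3p = 0L, dideoxy_3p = FALSE) {
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("role", "length") %in% names(segments)), nrow(segments) >= 1)
  if (!"sequence" %in% names(segments)) segments$sequence <- NA_character_
  structure(list(segments = segments,
                 phosphorothioate_3p = as.integer(phosphorothioate_3p),
                 dideoxy_3p = isTRUE(dideoxy_3p)),
            class = "oligo_spec")
}

#' The default 80-base capture-oligo architecture
#'
#' A modified TotalSeq-B style design: a 34-base 5' PCR handle, 7 random
#' spacer bases, an 11-base unique antibody barcode, 6 random spacer bases
#' and a 22-base 3' bead-capture sequence whose final two adenines are
#' phosphorothioated.
#'
#' @param barcode Optional 11-base barcode sequence to fill the barcode
#'   segment (see [incite_barcodes()]).
#' @return An [oligo_spec()].
#' @export
default_oligo_spec <- function(barcode = NA_character_) {
  oligo_spec(tibble::tribble(
    ~role,        ~length, ~sequence,
    "pcr_handle", 34L,     "GTGACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
    "spacer",     7L,      NA_character_,
    "barcode",    11L,     barcode,
    "spacer",     6L,      NA_character_,
    "capture",    22L,     "GCTTTAAGGCCGGTCCTAGCAA"
  ), phosphorothioate_3p = 2L)
}

#' The three antibody barcodes of the default panels
#'
#' @return Named character vector of 11-base barcodes.
#' @export
incite_barcodes <- function() {
  c(barcode1 = "GTCACTACGAG",
    barcode2 = "TGGCTACAAGT",
    barcode3 = "CGACATTGACA")
}

#' Validate an oligo specification
#'
#' Sums declared segment lengths and checks every supplied sequence against
#' its declared length. Mismatches are reported as failures in the returned
#' report rather than errors.
#'
#' @param spec An [oligo_spec()].
#' @return A list: `total_length`, `segments` (tibble with per-segment
#'   `ok`), `failures` (character), `phosphorothioate_3p`, `dideoxy_3p`,
#'   `valid`.
#' @export
validate_oligo <- function(spec) {
  stopifnot(inherits(spec, "oligo_spec"))
  seg <- dplyr::mutate(spec$segments,
    seq_length = ifelse(is.na(.data$sequence), NA_integer_, nchar(.data$sequence)),
    ok = is.na(.data$sequence) | nchar(.data$sequence) == .data$length)
  failures <- sprintf("segment %d (%s): declared %d bases but sequence has %d",
                      which(!seg$ok), seg$role[!seg$ok],
                      seg$length[!seg$ok], seg$seq_length[!seg$ok])
  list(total_length = sum(seg$length), segments = seg, failures = failures,
       phosphorothioate_3p = spec$phosphorothioate_3p,
       dideoxy_3p = spec$dideoxy_3p, valid = !length(failures))
}

#' Pairwise Hamming distances between barcodes
#'
#' @param barcodes Named character vector of equal-length sequences.
#' @return A list: `distances` (symmetric integer matrix, zero diagonal)
#'   and `min_distance` (minimum off-diagonal distance; `NA` for a single
#'   barcode).
#' @export
barcode_distances <- function(barcodes = incite_barcodes()) {
  lens <- nchar(barcodes)
  if (length(unique(lens)) > 1) {
    abort("barcodes must all have the same length", class = "inciteseq_config_error")
  }
  n <- length(barcodes)
  chars <- strsplit(barcodes, "", fixed = TRUE)
  d <- matrix(0L, n, n, dimnames = list(names(barcodes), names(barcodes)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(chars[[i]] != chars[[j]])
    }
  }
  list(distances = d,
       min_distance = if (n > 1) min(d[upper.tri(d)]) else NA_integer_)
}

#' Conjugation stoichiometry plan
#'
#' Computes the volumes and masses for conjugating an antibody with
#' oligo-bearing photo-crosslinking linkers (oYo-link) and saturating the
#' single-stranded oligo with E. coli single-stranded-DNA-binding protein
#' (EcoSSB): at the stock molarity (33 uM by default) one microlitre of
#' linker carries `molarity x 1e-6 L` moles (3.3e-11 mol at default);
#' linker moles are `ratio x` antibody moles; EcoSSB moles are
#' `ecossb_fold x` linker moles (12-fold by default, chosen to saturate
#' the ~35 bases an EcoSSB tetramer covers with excess), converted to
#' micrograms via the monomer molar mass.
#'
#' @param ab_mass_ug Antibody mass (micrograms).
#' @param ab_molar_mass Antibody molar mass (g/mol; 150,000 for IgG).
#' @param oyo_molarity Linker stock molarity (mol/L).
#' @param ratio Linker : antibody molar ratio.
#' @param ecossb_fold EcoSSB : linker molar ratio.
#' @param ecossb_monomer_mass EcoSSB monomer molar mass (g/mol).
#' @return A `conjugation_plan` list: `ab_moles`, `oyo_moles`,
#'   `oyo_moles_per_uL`, `oyo_volume_uL`, `ecossb_moles`, `ecossb_mass_ug`,
#'   `ecossb_ug_per_uL_oyo` plus the echoed inputs.
#' @export
conjugation_plan <- function(ab_mass_ug, ab_molar_mass = 150000,
                             oyo_molarity = 33e-6, ratio = 5,
                             ecossb_fold = 12, ecossb_monomer_mass = 18900) {
  inputs <- c(ab_mass_ug, ab_molar_mass, oyo_molarity, ratio, ecossb_fold,
              ecossb_monomer_mass)
  if (any(!is.finite(inputs)) || any(inputs <= 0)) {
    abort("all conjugation inputs must be positive", class = "inciteseq_config_error")
  }
  oyo_moles_per_uL <- oyo_molarity * 1e-6       # mol per microlitre
  ab_moles <- ab_mass_ug * 1e-6 / ab_molar_mass
  oyo_moles <- ratio * ab_moles
  oyo_volume_uL <- oyo_moles / oyo_moles_per_uL
  ecossb_moles <- ecossb_fold * oyo_moles
  ecossb_mass_ug <- ecossb_moles * ecossb_monomer_mass * 1e6
  structure(list(
    ab_mass_ug = ab_mass_ug, ab_molar_mass = ab_molar_mass,
    oyo_molarity = oyo_molarity, ratio = ratio, ecossb_fold = ecossb_fold,
    ecossb_monomer_mass = ecossb_monomer_mass,
    ab_moles = ab_moles, oyo_moles = oyo_moles,
    oyo_moles_per_uL = oyo_moles_per_uL, oyo_volume_uL = oyo_volume_uL,
    ecossb_moles = ecossb_moles, ecossb_mass_ug = ecossb_mass_ug,
    ecossb_ug_per_uL_oyo = ecossb_fold * oyo_moles_per_uL *
      ecossb_monomer_mass * 1e6
  ), class = "conjugation_plan")
}

#' @export
print.conjugation_plan <- function(x, ...) {
  cat(sprintf(
    "<conjugation_plan> %.3g ug Ab -> %.3g uL oYo-link (1:%g), %.3g ug EcoSSB (%gx)\n",
    x$ab_mass_ug, x$oyo_volume_uL, x$ratio, x$ecossb_mass_ug, x$ecossb_fold))
  invisible(x)
}

#' Self-complementarity scan of a blocking oligo
#'
#' Checks whether any window of `min_len` bases is reverse-complementary to
#' another window of the same sequence (a proxy for hairpin/self-dimer
#' potential), and reports the 3'-terminator flag.
#'
#' @param sequence DNA sequence (A/C/G/T).
#' @param min_len Window length scanned.
#' @param dideoxy_3p Whether the 3' end is a dideoxy terminator.
#' @return A list: `self_complementary` (logical), `n_windows_hit`,
#'   `dideoxy_3p`.
#' @export
scan_blocking_oligo <- function(sequence, min_len = 6L, dideoxy_3p = TRUE) {
  s <- toupper(sequence)
  comp <- chartr("ACGT", "TGCA", s)
  rc <- paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  n <- nchar(s)
  hits <- 0L
  if (n >= min_len) {
    for (i in seq_len(n - min_len + 1L)) {
      w <- substr(s, i, i + min_len - 1L)
      if (grepl(w, rc, fixed = TRUE)) hits <- hits + 1L
    }
  }
  list(self_complementary = hits > 0L, n_windows_hit = hits,
       dideoxy_3p = isTRUE(dideoxy_3p))
}
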