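# inciteseq

Analysis toolkit for **intracellular CITE-seq** experiments: single-cell
assays in which oligonucleotide-tagged antibodies against intracellular
phospho-epitopes (antibody-derived tags, ADTs) are sequenced alongside gene
expression and sample-indexing hashtag oligos from the same cells. It is
written for analysts working with multiplexed stimulated-versus-control
designs — the motivating case is Th17 cell cultures probed for p-STAT3,
p-p65, p-ERK1/2 and p-FOS across two antibody panels — who need the full
path from raw count matrices to phospho-state-resolved differential
expression and validation against flow cytometry.

## What it computes

Given gene / ADT / hashtag count matrices over one cell-barcode axis (read
from CellRanger-style Matrix Market directories), the pipeline performs:

1. **Hashtag demultiplexing** — per-hashtag positive-staining cutoffs
   (deterministic 1-D two-means on log counts, or quantile/Otsu/manual),
   then rule-based calls: *doublet* if positive for ≥ 2 identity hashes or
   both condition hashes; *unassigned* if missing either hash class;
   otherwise a *singlet* assigned to condition x culture x panel.
2. **Quality control** — per-cell counts, detected genes and mitochondrial
   fraction, filtered at ≥ 500 genes, ≥ 500 counts, mito ≤ 0.1 (inclusive),
   plus a marker-score flag for a contaminating B-cell-like population.
3. **Isotype-corrected phospho quantification** — per (culture, condition)
   group the median raw isotype-control count *m* estimates nonspecific
   background; each phospho count *a* becomes
   `v = ln(1 + max(0, a − m))`, and a cell is positive iff `v > 0`
   (equivalently `a > m`). Cells are annotated with a combinatorial
   phospho-state per two-target panel (unphosphorylated / single:<target> /
   double) and summarised per sample as percent positivity and mean
   corrected level.
4. **Differential expression** — cluster-wise size-factor normalization
   (`y = ln(1 + a/s_c)`) and a two-part **hurdle** likelihood-ratio test per
   gene: a ridge-stabilised logistic model of detection plus a Gaussian
   model of positive expression, statistics summed and referred to a
   chi-square with one df per estimable component, with a detection-rate
   covariate (ln genes per cell), `min_pct = 0.01` gene filtering, group-mean
   log fold changes on the natural-log scale, and Benjamini–Hochberg
   adjustment.
5. **Signed gene-set intersections** — DEG lists as (gene, direction) sets
   partitioned into exclusive upset-style signatures.
6. **Flow concordance** — per-target ordinary least squares of flow percent
   positivity (and MFI) on the sequencing summaries, reporting slope,
   intercept, R² and an F-test p-value.
7. **Reagent design** — validation of the 80-base antibody-oligo
   architecture, barcode Hamming distances, and conjugation stoichiometry
   (antibody : linker molar ratio, single-stranded-DNA-binding-protein
   dosing).

A fully parameterised synthetic generator (`generate_dataset()`) emulates
the 12-sample hashing design with ground truth — negative-binomial counts,
state-coupled gene programs, isotype-like backgrounds, cross-sample
doublets, a ~7% contaminant population — so every stage is testable without
sequencer output, and `run_pipeline()` orchestrates all stages from one
seeded configuration with a consolidated JSON report.

## Worked example

```r
library(inciteseq)

cfg <- generator_config(n_cells_per_sample = 250, seed = 42)
ds  <- generate_dataset(cfg)                        # rna / adt / hto + truth

cuts <- estimate_hash_cutoffs(ds$hto)
ann  <- classify_cells(ds$hto, cuts, cfg$design)
table(ann$status)
#> doublet singlet
#>     247    2753

qc  <- compute_qc_metrics(ds$rna)
ann$pass_qc     <- apply_qc(qc, qc_thresholds())
ann$contaminant <- flag_contaminants(ds$rna)

med <- compute_isotype_medians(ds$adt, ann, cfg$design)
med
#> # A tibble: 6 x 4
#>   culture  condition    isotype_median n_cells
#> 1 cultureA stimulated                4     210
#> 2 cultureA unstimulated              3     207
#> 3 cultureB stimulated                4     215
#> ...
```

The six group medians land in the 3–5 range the isotype background is
parameterised to produce. Correcting and summarising:

```r
quant <- correct_and_call(ds$adt, med, cfg$design, ann)
summ  <- summarize_per_sample(quant)
dplyr::filter(summ, target_id == "p-FOS")
#>   sample_id             target_id percent_positive mean_corrected
#> 1 cultureA_stimulated   p-FOS                81.4           3.23
#> 2 cultureA_unstimulated p-FOS                11.3           0.310
#> 3 cultureB_stimulated   p-FOS                80.4           3.19
#> ...
```

The stimulated/unstimulated split mirrors the generator's configured p-FOS
fractions (86.4% vs 5.42%, scaled per culture). Regressing a paired flow
table against these summaries:

```r
flow <- generate_flow_table(ds$truth, noise_sd = 1, seed = 7)
fits <- compare_modalities(summ, flow)
dplyr::filter(tidy(fits), axis == "percent_positive")
#>   target_id axis                 n slope intercept r_squared          p
#> 1 p-ERK1/2  percent_positive     6  1.02    -1.14      0.994 0.0000129
#> 2 p-FOS     percent_positive     6  1.04    -3.74      0.998 0.00000126
#> 3 p-p65     percent_positive     6  1.14    -5.15      0.944 0.00122
#> 4 p-STAT3   percent_positive     6  1.01     0.263     0.978 0.000179
```

Slopes near 1 and R² near 1 show the sequencing summaries track the
(noisy) flow measurements across all six samples per target. The reagent
arithmetic is a one-liner:

```r
conjugation_plan(ab_mass_ug = 1)
#> <conjugation_plan> 1 ug Ab -> 1.01 uL oYo-link (1:5), 7.56 ug EcoSSB (12x)
```

`autoplot()` methods and `plot_*()` helpers (hash cutoff histograms,
phospho-level densities, volcano plots, intersection bars, concordance
scatters) give ggplot2 renderings of each result type; `tidy()` and
`glance()` return tibbles for downstream use.

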