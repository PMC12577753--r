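Package: inciteseq
Title: Intracellular CITE-Seq Quantification with Multimodal Concordance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-cell experiments that read out
    intracellular phospho-epitopes with oligonucleotide-tagged antibodies
    alongside gene expression (intracellular CITE-seq). Provides hashtag
    demultiplexing with explicit doublet rules, per-cell quality control,
    isotype-control background correction and positivity calling,
    combinatorial phospho-state annotation, cluster-wise size-factor
    normalization, a two-part (hurdle) differential-expression test with a
    detection-rate covariate, signed gene-set intersection partitioning,
    cross-modality concordance regression against flow cytometry, a fully
    parameterised multimodal synthetic data generator with ground truth, and
    antibody-oligonucleotide conjugation design arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
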