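Package: crossatlas
Title: Cross-Species Comparison of Single-Nucleus Brain Cell Atlases
Version: 0.9.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Post-clustering toolkit for single-nucleus RNA-seq cell atlases
    spanning several species and adult phenotypes. Provides spliced-alignment
    filtering against canonical intron motifs, nucleus-level quality control,
    CP10K normalization, per-cluster expression summaries, rank-sum marker and
    differentially-expressed-gene calling, reciprocal-best-hit orthology with
    priority-based GO transfer and Fisher over-representation tests,
    pseudo-cell neighbour-voting mean-AUROC cell-type correspondence between
    datasets, replicate-aware Dirichlet-multinomial compositional
    differential-abundance testing with convergence calls, and a synthetic
    atlas generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    data.table,
    jsonlite,
    yaml,
    ape,
    igraph,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
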