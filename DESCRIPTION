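Package: kacscan
Title: Epithelial Cell-State Analysis for Early Lung Adenocarcinoma Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting epithelial cell states in early lung
    adenocarcinoma single-cell and spatial transcriptomics cohorts:
    cell-level quality filtering, barcode-aware somatic variant genotyping
    (per-cell allele tallies, subpopulation variant-allele frequency and
    mutant-cell fraction), expression-derived copy-number burden scores at
    arm, cell and spot level, marker-panel lineage assignment with
    KRT8+ alveolar intermediate cell (KAC) calling, binned-control gene
    signature scoring, two-component Gaussian mixture dichotomization of
    differentiation scores, resampled Bhattacharyya transcriptome-similarity
    statistics, a one-dimensional Wasserstein variability statistic, and
    Visium-style hexagonal neighborhood composition. A seeded synthetic-data
    generator emulates multi-population alveolar cohorts (AT1/AT2/AIC/KAC/
    malignant) with marker programs, arm-level copy-number events, per-cell
    mutant reads and spot lattices, so the whole pipeline is testable
    without controlled-access patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rsamtools,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
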