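Package: striatoglia
Title: Oligodendroglia Single-Nucleus and Spatial Analysis for the Parkinsonian Striatum
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Reusable implementation of a single-nucleus RNA-seq and spatial
    transcriptomics analysis pipeline for oligodendroglia in the dorsal
    striatum: a multi-stage nuclei quality-control cascade (consensus doublet
    calls, hard count thresholds, polynomial gene~UMI outlier detection,
    Gaussian-mixture marker-score doublet removal, regional contamination
    filtering), marker-based lineage annotation with one-vs-rest Wilcoxon
    marker ranking, per-sample compositional statistics and ratio-intensity
    correlations, preranked gene set enrichment analysis with permutation
    nulls and cross-contrast superpathway aggregation, permutation z-score
    spatial neighborhood enrichment, and histology region-of-interest
    statistics. A seeded synthetic-cohort generator with planted ground truth
    makes every stage testable without access to donor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
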