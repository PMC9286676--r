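Package: scCoupling
Title: Cell-Type-Resolved Receptor Co-Expression Coupling Scores for
    Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies cell-type-resolved co-expression between nuclear
    receptor genes (such as the corticosteroid receptors Nr3c1 and Nr3c2)
    and curated gene sets in single-cell RNA-seq data. Provides Matrix
    Market input/output, quality-control filtering and log-normalization,
    per-cell-type pseudobulk expression profiles with percent-positive
    statistics, a gene-set-normalized coupling score for ranking pairwise
    co-expression across cell types, a multi-evidence consensus filter
    that calls receptor target genes from transcriptomic and ChIP-seq
    evidence tables, one-vs-rest Wilcoxon marker statistics, and a seeded
    negative-binomial count simulator with planted co-expression structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, Coverage
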