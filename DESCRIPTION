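Package: isletAging
Title: Single-Cell Analysis of Primate Pancreatic Islet Aging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing aging in pancreatic islet single-cell
    RNA-seq data. Implements endocrine cell typing from canonical hormone
    markers, a per-cell transcriptional-noise statistic with young-versus-old
    group tests, discovery of aging-associated differentially expressed genes
    along an age-separating principal component that is consistent across
    donors, gene-set aging scores and enrichment tests, ligand-receptor
    interaction scoring with an empirical cell-type-label permutation test,
    and correlation-based regulatory-network hub ranking. Ships a negative
    binomial UMI count simulator with planted ground truth (cell types, donor
    batch effects, aging expression programs, noise inflation, ligand-receptor
    pairs and a hub regulator) so that every stage of the pipeline can be
    validated against known structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    irlba,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, RNASeq
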