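suppressPackageStartupMessages({
    library(SingleCellExperiment)
})

# small four-type dataset for fast unit tests (shared, built once)
.tinyConfig <- function(...) {
    simConfig(nCellsTotal = 400L, nGenes = 600L, seed = 42L, ...)
}

.cache <- new.env(parent = emptyenv())

tinyDataset <- function() {
    if (is.null(.cache$tiny)) {
        sce <- simulateIslets(.tinyConfig(), seed = 42)
        .cache$tiny <- normalizeLog(qcFilter(sce, 50, 100)$sce)
    }
    .cache$tiny
}

# larger dataset with enough beta cells per donor for aging-axis work
axisDataset <- function() {
    if (is.null(.cache$axis)) {
        cfg <- simConfig(nCellsTotal = 1500L, nGenes = 700L,
                         typeProportions = c(alpha = 0.3, beta = 0.4,
                                             delta = 0.15, PP = 0.15),
                         noiseInflation = c(alpha = 1, beta = 1, delta = 1,
                                            PP = 1),
                         seed = 42L)
        sce <- simulateIslets(cfg, seed = 42)
        .cache$axis <- normalizeLog(qcFilter(sce, 50, 100)$sce)
    }
    .cache$axis
}

# single-type null dataset (no planted structure, no donor effects)
nullDataset <- function(seed = 7, nCells = 200L, nGenes = 300L,
                        donorEffectSd = 0) {
    cfg <- simConfig(nCellsTotal = nCells, nGenes = nGenes,
                     typeProportions = c(alpha = 1),
                     donorEffectSd = donorEffectSd, seed = 1L)
    normalizeLog(qcFilter(simulateIslets(cfg, seed = seed), 30, 60)$sce)
}

jaccard <- function(a, b) {
    u <- union(a, b)
    if (!length(u)) return(NA_real_)
    length(intersect(a, b)) / length(u)
}

# SCE from an explicit logcounts matrix (genes x cells) for hand fixtures
sceFromLogcounts <- function(ln, meta = NULL) {
    if (is.null(rownames(ln))) rownames(ln) <- paste0("g", seq_len(nrow(ln)))
    if (is.null(colnames(ln))) colnames(ln) <- paste0("c", seq_len(ncol(ln)))
    cd <- if (is.null(meta))
        S4Vectors::DataFrame(cell_id = colnames(ln), row.names = colnames(ln))
    else S4Vectors::DataFrame(meta, row.names = colnames(ln))
    sce <- SingleCellExperiment(
        assays = list(counts = matrix(as.integer(ln > 0), nrow(ln),
                                      ncol(ln), dimnames = dimnames(ln)),
                      logcounts = ln),
        colData = cd)
    sce
}
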