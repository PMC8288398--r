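test_that("matrix bundles round-trip exactly", {
    sce <- tinyDataset()
    dir <- withr::local_tempdir()
    writeMatrixBundle(sce, dir)
    back <- readMatrixBundle(dir)
    expect_identical(unname(as.matrix(counts(back))),
                     unname(as.matrix(counts(sce))))
    expect_identical(rownames(back), rownames(sce))
    expect_identical(colnames(back), colnames(sce))
    expect_identical(back$age_group, sce$age_group)
})

test_that("toy bundles load and inconsistent metadata is reported", {
    dir <- withr::local_tempdir()
    m <- matrix(c(0L, 1L, 2L, 3L, 4L, 5L), 3, 2,
                dimnames = list(paste0("g", 1:3), c("c1", "c2")))
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
    meta <- data.frame(cell_id = c("c1", "c2"), donor_id = "d1",
                       age_group = "young", sex = "F")
    write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sce <- readMatrixBundle(dir)
    expect_equal(dim(sce), c(3L, 2L))
    # drop one cell from the metadata: the error names it
    write.table(meta[1, ], file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    expect_error(readMatrixBundle(dir), "c2")
})

test_that("qc filtering drops failing cells, keeps genes, and is idempotent", {
    sce <- tinyDataset()
    # degenerate cell with zero counts is removed at min_counts = 1
    m <- counts(sce)
    m[, 1] <- 0L
    sce0 <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m), colData = colData(sce))
    qc <- qcFilter(sce0, minGenes = 0, minCounts = 1)
    expect_false(colnames(sce)[1] %in% colnames(qc$sce))
    expect_equal(nrow(qc$report), ncol(sce0))
    # identity filter
    qcId <- qcFilter(sce, minGenes = 0, minCounts = 0)
    expect_equal(ncol(qcId$sce), ncol(sce))
    expect_equal(nrow(qcId$sce), nrow(sce))
    # idempotence
    once <- qcFilter(sce, minGenes = 100, minCounts = 500)
    twice <- qcFilter(once$sce, minGenes = 100, minCounts = 500)
    expect_identical(colnames(twice$sce), colnames(once$sce))
    expect_true(all(twice$report$kept))
    expect_error(qcFilter(sce, minGenes = -1), "non-negative")
})

test_that("log normalization scales cells exactly and follows gene order", {
    m <- matrix(c(1L, 1L, 2L), 3, 1,
                dimnames = list(paste0("g", 1:3), "c1"))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m))
    ln <- logcounts(normalizeLog(sce, scale = 4))
    expect_equal(as.vector(ln), log2(c(2, 2, 3)))
    # conservation: de-logged values sum to the scale
    sce2 <- tinyDataset()
    delog <- 2^logcounts(sce2) - 1
    expect_equal(unname(colSums(delog)), rep(1e5, ncol(sce2)),
                 tolerance = 1e-6)
    # permuting gene order permutes values with their ids
    perm <- sample(nrow(sce2))
    raw <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts(sce2)))
    lnP <- logcounts(normalizeLog(raw[perm, ]))
    expect_equal(lnP, logcounts(sce2)[perm, ])
    # zero-count cell refused
    m0 <- matrix(0L, 2, 1, dimnames = list(c("a", "b"), "c1"))
    expect_error(normalizeLog(SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m0))), "zero total")
})

test_that("expression fractions count positive cells", {
    ln <- matrix(0, 2, 8, dimnames = list(c("zero", "some"), NULL))
    ln["some", 1:3] <- 1
    sce <- sceFromLogcounts(ln)
    expect_equal(expressionFraction(sce, "zero"), 0)
    expect_equal(expressionFraction(sce, "some"), 0.375)
    ln2 <- ln; ln2["zero", ] <- 2
    expect_equal(expressionFraction(sceFromLogcounts(ln2), "zero"), 1)
    expect_error(expressionFraction(sce, "nope"), "unknown gene")
    expect_error(expressionFraction(sce, "some", cells = character(0)),
                 "empty")
})

test_that("GMT and table readers parse their formats", {
    dir <- withr::local_tempdir()
    gmt <- file.path(dir, "sets.gmt")
    writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), gmt)
    sets <- readGMT(gmt)
    expect_named(sets, c("setA", "setB"))
    expect_equal(sets$setA, c("g1", "g2", "g3"))
    mk <- file.path(dir, "markers.tsv")
    writeLines(c("gene\tcell_type", "GCG\talpha"), mk)
    expect_equal(readMarkerSpec(mk)$gene, "GCG")
    lr <- file.path(dir, "pairs.tsv")
    writeLines(c("ligand\treceptor", "TTR\tDDR1", "TTR\tDDR1"), lr)
    expect_equal(nrow(readLRPairs(lr)), 1L)
})
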