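test_that("PCA returns orthonormal loadings and complete reconstructions", {
    set.seed(2)
    ln <- matrix(rnorm(30 * 25), 30, 25)
    sce <- sceFromLogcounts(ln)
    pca <- fitPCA(sce, nComponents = 10L, scale = FALSE)
    L <- pca$loadings
    expect_equal(crossprod(L), diag(10), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(pca$varianceExplained) <= 1e-12))
    # full-rank reconstruction reproduces the centered data
    full <- fitPCA(sce, nComponents = 25L, scale = FALSE)
    centered <- t(ln - rowMeans(ln))
    rec <- full$scores %*% t(full$loadings)
    expect_equal(unname(rec), unname(centered), tolerance = 1e-6)
    # rank-1 structure is fully captured by PC1
    rank1 <- outer(rnorm(30), rnorm(25)) + 1e-8 * matrix(rnorm(750), 30)
    p1 <- fitPCA(sceFromLogcounts(rank1), nComponents = 3L, scale = FALSE)
    expect_gt(p1$varianceExplained[1], 0.999)
    expect_error(fitPCA(sce, nComponents = 40L), "rank|cells")
})

test_that("flipping age labels flips orientation but not the selected PC", {
    sce <- axisDataset()
    cells <- colnames(sce)[sce$cell_type == "beta"]
    meta <- as.data.frame(colData(sce)[cells, ])
    pca <- fitPCA(sce, cells, seed = 1)
    ax <- selectAgePC(pca, meta, "beta")
    expect_s4_class(ax, "AgingAxis")
    metaF <- meta
    metaF$age_group <- ifelse(meta$age_group == "old", "young", "old")
    axF <- selectAgePC(pca, metaF, "beta")
    expect_equal(axisPC(axF), axisPC(ax))
    expect_equal(axF@orientation, -ax@orientation)
    expect_equal(axisScores(axF), -axisScores(ax))
    expect_equal(axisAUC(axF), axisAUC(ax), tolerance = 1e-12)
})

test_that("age-state assignment never crosses donor age groups", {
    sce <- axisDataset()
    r <- agingAxisDEGs(sce, "beta", seed = 1)
    expect_s4_class(r$axis, "AgingAxis")
    st <- merge(r$assignment, as.data.frame(colData(sce)), by = "cell_id")
    expect_true(all(st$age_group[st$state == "old-like"] == "old"))
    expect_true(all(st$age_group[st$state == "young-like"] == "young"))
    # perfectly separated scores exclude nobody
    meta <- data.frame(cell_id = paste0("c", 1:8), donor_id = rep(c("y","o"), each = 4),
                       age_group = rep(c("young", "old"), each = 4))
    ax <- new("AgingAxis", cellType = "t", pcIndex = 1L, orientation = 1,
              scores = setNames(c(-4, -3, -2.5, -2, 2, 2.5, 3, 4),
                                meta$cell_id),
              auc = 1, donorMedians = data.frame(), loading = c(g = 1),
              midpoint = 0)
    a <- assignAgeStates(ax, meta)
    expect_false(any(a$state == "excluded"))
    # a young-donor cell above the midpoint is excluded, never old-like
    ax@scores["c1"] <- 5
    a2 <- assignAgeStates(ax, meta)
    expect_equal(a2$state[a2$cell_id == "c1"], "excluded")
})

test_that("identical groups yield no DEGs and swapped groups flip direction", {
    sce <- tinyDataset()
    cells <- colnames(sce)[sce$cell_type == "alpha"][1:40]
    expect_equal(nrow(callDEGs(sce, cells, cells)), 0L)
    old <- colnames(sce)[sce$cell_type == "beta" & sce$age_group == "old"]
    young <- colnames(sce)[sce$cell_type == "beta" & sce$age_group == "young"]
    a <- callDEGs(sce, old, young)
    b <- callDEGs(sce, young, old)
    expect_setequal(a$gene, b$gene)
    m <- match(a$gene, b$gene)
    expect_equal(a$log2fc, -b$log2fc[m])
    expect_equal(a$p, b$p[m])
    expect_true(all(a$direction[a$log2fc > 0] == "up"))
    expect_error(callDEGs(sce, old[1], young), ">= 2")
})

test_that("DEG p-values are uniform when labels carry no signal", {
    sce <- nullDataset(seed = 12, nCells = 150L, nGenes = 500L)
    cells <- colnames(sce)
    fake <- isletAging:::.withSeed(3, sample(cells))
    tab <- callDEGs(sce, fake[1:75], fake[76:150], all = TRUE)
    keep <- tab$p < 1  # drop degenerate all-tied genes
    ks <- suppressWarnings(stats::ks.test(tab$p[keep], "punif"))
    expect_gt(ks$p.value, 0.01)
})

test_that("set overlaps are exact", {
    ov <- overlapSets(c("a", "b", "c"), c("b", "c", "d"))
    expect_equal(ov$nA_only, 1L)
    expect_equal(ov$n_shared, 2L)
    expect_equal(ov$nB_only, 1L)
    expect_setequal(ov$shared, c("b", "c"))
    same <- overlapSets(letters[1:3], letters[1:3])
    expect_equal(same$nA_only + same$nB_only, 0L)
    expect_equal(overlapSets(letters[1:3], letters[5:7])$n_shared, 0L)
})

test_that("sex-stratified analysis warns on a single-sex input", {
    sce <- axisDataset()
    males <- sce[, sce$sex == "M"]
    expect_warning(res <- stratifiedDEGs(males, "beta", seed = 1),
                   "lacks an age group|no consistent aging axis|fewer than two strata")
    expect_lte(length(res$per_stratum), 1L)
    expect_null(res$overlap_up)
})

test_that("axis recovery strengthens with the planted effect size", {
    aucs <- vapply(c(0.25, 0.5, 1.0), function(ef) {
        prog <- data.frame(gene = sprintf("g%05d", 101:160),
                           cell_type = "alpha", log2fc = ef)
        cfg <- simConfig(nCellsTotal = 500L, nGenes = 800L,
                         typeProportions = c(alpha = 1),
                         agingProgram = prog, donorEffectSd = 0.1,
                         seed = 21L)
        sce <- normalizeLog(qcFilter(simulateIslets(cfg, seed = 21), 50,
                                     100)$sce)
        pca <- fitPCA(sce, nComponents = 10L, seed = 1)
        ax <- selectAgePC(pca, as.data.frame(colData(sce)), "alpha")
        if (is.null(ax)) 0.5 else axisAUC(ax)
    }, 0)
    expect_true(all(diff(aucs) >= 0))
    expect_gt(aucs[3], 0.9)
})

test_that("a program planted in both sexes is recovered in both strata", {
    sce <- axisDataset()
    res <- stratifiedDEGs(sce, "beta", seed = 1)
    expect_equal(length(res$per_stratum), 2L)
    ov <- res$overlap_up
    expect_false(is.null(ov))
    shared <- ov$n_shared / (ov$nA_only + ov$n_shared + ov$nB_only)
    expect_gt(shared, 0.6)
})
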