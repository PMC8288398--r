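test_that("noise equals the hand-computed distance to the group centroid", {
    # two cells at (0,0) and (2,2): centroid (1,1); distance sqrt(2),
    # normalized by sqrt(2) genes -> noise 1 for both
    ln <- matrix(c(0, 0, 2, 2), 2, 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
    meta <- data.frame(cell_id = c("c1", "c2"), donor_id = "d",
                       age_group = c("young", "young"), cell_type = "alpha")
    # add an old pair so the type has both groups
    ln <- cbind(ln, c3 = c(1, 1), c4 = c(3, 3))
    meta <- rbind(meta, data.frame(cell_id = c("c3", "c4"), donor_id = "d2",
                                   age_group = "old", cell_type = "alpha"))
    sce <- sceFromLogcounts(ln, meta)
    nv <- transcriptionalNoise(sce, "alpha", fracMin = 0)
    expect_equal(nv$noise[nv$cell_id %in% c("c1", "c2")], c(1, 1))
    # all cells identical -> zero noise
    lnZ <- matrix(2, 2, 4, dimnames = dimnames(ln))
    nvZ <- transcriptionalNoise(sceFromLogcounts(lnZ, meta), "alpha",
                                fracMin = 0)
    expect_equal(nvZ$noise, rep(0, 4))
    # homogeneity: doubling expression doubles noise
    nv2 <- transcriptionalNoise(sceFromLogcounts(2 * ln, meta), "alpha",
                                fracMin = 0)
    expect_equal(nv2$noise, 2 * nv$noise)
})

test_that("noise ignores gene order and genes below the detection filter", {
    sce <- tinyDataset()
    nv <- transcriptionalNoise(sce, "beta", fracMin = 0.2)
    perm <- sample(nrow(sce))
    nvP <- transcriptionalNoise(sce[perm, ], "beta", fracMin = 0.2)
    expect_equal(nv$noise, nvP$noise)
    # appending genes below fracMin changes nothing
    ln <- logcounts(sce)
    rare <- matrix(0, 5, ncol(sce),
                   dimnames = list(paste0("rare", 1:5), colnames(sce)))
    rare[, 1] <- 1e-3
    sceR <- sceFromLogcounts(rbind(ln, rare), as.data.frame(colData(sce)))
    nvR <- transcriptionalNoise(sceR, "beta", fracMin = 0.2)
    expect_equal(nvR$noise, nv$noise)
})

test_that("the old-young noise test matches a textbook Welch computation", {
    noise <- data.frame(cell_id = paste0("c", 1:6),
                        donor_id = "d",
                        age_group = rep(c("old", "young"), each = 3),
                        noise = c(1.3, 1.1, 1.6, 0.9, 1.0, 0.8))
    attr(noise, "cell_type") <- "alpha"
    res <- compareNoise(noise)
    x <- noise$noise[1:3]; y <- noise$noise[4:6]
    se <- sqrt(var(x) / 3 + var(y) / 3)
    tManual <- (mean(x) - mean(y)) / se
    df <- se^4 / ((var(x) / 3)^2 / 2 + (var(y) / 3)^2 / 2)
    expect_equal(res$t, tManual)
    expect_equal(res$p, 2 * pt(-abs(tManual), df))
    # identical distributions: t = 0, p = 1
    same <- noise; same$noise <- rep(c(1, 2, 3), 2)
    resS <- compareNoise(same)
    expect_equal(resS$t, 0)
    expect_equal(resS$p, 1)
})

test_that("noise-correlated genes match a brute-force per-gene loop", {
    sce50 <- normalizeLog(qcFilter(simulateIslets(
        simConfig(nCellsTotal = 40L, nGenes = 50L,
                  typeProportions = c(alpha = 1), seed = 8L),
        seed = 8), 5, 10)$sce)
    nv <- transcriptionalNoise(sce50, "alpha", fracMin = 0)
    tab <- noiseCorrelatedGenes(sce50, nv)
    ln <- logcounts(sce50)[, nv$cell_id]
    for (i in seq_len(nrow(ln))) {
        g <- rownames(ln)[i]
        row <- tab[tab$gene == g, ]
        if (sd(ln[i, ]) == 0) {
            expect_true(is.na(row$r))
            expect_false(row$passes)
        } else {
            ct <- cor.test(ln[i, ], nv$noise)
            expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
            expect_equal(row$p, ct$p.value, tolerance = 1e-12)
        }
    }
    expect_equal(tab$passes,
                 !is.na(tab$r) & tab$r > 0.6 & tab$fdr <= 0.05)
})

test_that("only positive noise correlations can pass", {
    sce <- tinyDataset()
    nv <- transcriptionalNoise(sce, "beta")
    ln <- logcounts(sce)[, nv$cell_id]
    ln <- rbind(ln, noise_twin = nv$noise, noise_anti = -nv$noise)
    meta <- as.data.frame(colData(sce))[nv$cell_id, ]
    sceX <- sceFromLogcounts(ln, meta)
    tab <- noiseCorrelatedGenes(sceX, nv)
    expect_equal(tab$r[tab$gene == "noise_twin"], 1)
    expect_true(tab$passes[tab$gene == "noise_twin"])
    expect_equal(tab$r[tab$gene == "noise_anti"], -1)
    expect_false(tab$passes[tab$gene == "noise_anti"])
})

test_that("genes tracking a noise-coupled latent factor are recovered", {
    sce <- tinyDataset()
    nv <- transcriptionalNoise(sce, "beta")
    ln <- logcounts(sce)[, nv$cell_id]
    set.seed(11)
    tracking <- t(vapply(1:20, function(i)
        2 + 1.5 * scale(nv$noise)[, 1] + rnorm(nrow(nv), 0, 0.6), nv$noise))
    rownames(tracking) <- paste0("track", 1:20)
    meta <- as.data.frame(colData(sce))[nv$cell_id, ]
    sceX <- sceFromLogcounts(rbind(ln, tracking), meta)
    tab <- noiseCorrelatedGenes(sceX, nv)
    expect_gte(sum(tab$passes[grepl("^track", tab$gene)]), 16)
})

test_that("noise bins are rank-ordered and nearly equal in size", {
    noise <- data.frame(cell_id = paste0("c", 1:17),
                        donor_id = "d",
                        age_group = c(rep("old", 10), rep("young", 7)),
                        noise = c(10:1, 7:1) / 10)
    b <- binCellsByNoise(noise, 5)
    old <- b[b$age_group == "old", ]
    expect_equal(as.vector(table(old$bin)), rep(2L, 5))
    young <- b[b$age_group == "young", ]
    expect_equal(as.vector(table(young$bin)), c(2L, 2L, 1L, 1L, 1L))
    b3 <- binCellsByNoise(noise[noise$age_group == "young", ], 3)
    expect_equal(as.vector(table(b3$bin)), c(3L, 2L, 2L))
    # bin-mean noise is non-decreasing
    m <- tapply(noise$noise[match(old$cell_id, noise$cell_id)], old$bin, mean)
    expect_true(all(diff(m) >= 0))
    expect_error(binCellsByNoise(noise, 0), ">= 1")
})
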