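test_that("a singleton set reproduces the single-gene statistics", {
    sce <- tinyDataset()
    old <- colnames(sce)[sce$cell_type == "beta" & sce$age_group == "old"]
    young <- colnames(sce)[sce$cell_type == "beta" & sce$age_group == "young"]
    setRes <- genesetGroupTest(sce, "HSP90B1", old, young)
    geneRes <- geneGroupStats(sce, "HSP90B1", old, young)
    expect_equal(setRes$t, geneRes$t)
    expect_equal(setRes$p, geneRes$p)
    expect_equal(setRes$mean_A - setRes$mean_B, geneRes$log2fc)
    expect_equal(unname(setRes$score[old[1]]),
                 logcounts(sce)["HSP90B1", old[1]])
    # identical groups: t = 0
    same <- genesetGroupTest(sce, c("HSP90B1", "HSPA5"), old, old)
    expect_equal(same$t, 0)
    expect_error(genesetGroupTest(sce, "no_such_gene", old, young),
                 "no genes")
})

test_that("single-gene group statistics match a closed-form computation", {
    ln <- matrix(c(1, 2, 3, 5, 6, 7), 1, 6,
                 dimnames = list("g", paste0("c", 1:6)))
    sce <- sceFromLogcounts(rbind(ln, other = 0))
    res <- geneGroupStats(sce, "g", paste0("c", 4:6), paste0("c", 1:3))
    expect_equal(res$log2fc, 4)
    tt <- t.test(c(5, 6, 7), c(1, 2, 3))
    expect_equal(res$t, unname(tt$statistic))
    expect_equal(res$p, tt$p.value)
    # swapping groups negates the fold change, keeps the p-value
    swp <- geneGroupStats(sce, "g", paste0("c", 1:3), paste0("c", 4:6))
    expect_equal(swp$log2fc, -res$log2fc)
    expect_equal(swp$p, res$p)
})

test_that("fold-change matrices mask to genes differential somewhere", {
    sce <- axisDataset()
    truth <- simTruth(sce)
    betaUp <- truth@agingDEGs$gene[truth@agingDEGs$cell_type == "beta" &
                                   truth@agingDEGs$log2fc > 0][1:15]
    neutral <- setdiff(rownames(sce),
                       c(truth@agingDEGs$gene, truth@markerSpec$gene,
                         truth@hubRegulator$gene,
                         truth@hubRegulator$targets))[1:15]
    fc <- foldchangeMatrix(sce, c(betaUp, neutral))
    expect_true(all(rownames(fc) %in% c(betaUp, neutral)))
    expect_gte(sum(betaUp %in% rownames(fc)), 10)
    if (any(betaUp %in% rownames(fc)))
        expect_true(all(fc[intersect(betaUp, rownames(fc)), "beta"] > 0))
    # neutral genes rarely survive the mask
    expect_lte(sum(neutral %in% rownames(fc)), 3)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
    universe <- letters[1:20]
    set <- letters[1:5]
    hits <- letters[1:5]
    expect_equal(hypergeomEnrichment(hits, set, universe)$p, 1 / choose(20, 5))
    # saturation: hits = set = universe
    sat <- hypergeomEnrichment(universe, universe, universe)
    expect_equal(sat$overlap, 20L)
    expect_equal(sat$p, 1)
    # brute force over all draws for universe of 12
    uni <- letters[1:12]
    st <- letters[1:4]
    for (k in 0:3) {
        hits <- c(st[seq_len(k)], setdiff(uni, st)[seq_len(3 - k)])
        draws <- combn(12, 3)
        inSet <- matrix(draws <= 4, nrow = 3)
        pBrute <- mean(colSums(inSet) >= k)
        expect_equal(hypergeomEnrichment(hits, st, uni)$p, pBrute,
                     tolerance = 1e-12)
    }
    expect_error(hypergeomEnrichment(c("zz"), st, uni), "subset")
})

test_that("GSEA behaves at its analytic extremes", {
    set.seed(4)
    stats <- setNames(sort(rnorm(200), decreasing = TRUE), paste0("g", 1:200))
    topSet <- list(top = names(stats)[1:15])
    res <- gseaTest(stats, topSet, nPerm = 200, seed = 1)
    expect_gt(res$ES, 0.8)
    expect_lt(res$p, 0.02)
    # reversing the ranking negates the enrichment score
    resRev <- gseaTest(-stats, topSet, nPerm = 50, seed = 1)
    expect_lt(resRev$ES, 0)
    expect_equal(abs(resRev$ES), res$ES, tolerance = 1e-12)
    # random sets are unremarkable
    rnd <- list(r = paste0("g", seq(5, 200, by = 13)))
    resR <- gseaTest(stats, rnd, nPerm = 200, seed = 2)
    expect_gt(resR$p, 0.05)
    expect_error(gseaTest(stats, list(empty = "zzz")), "intersects")
})

test_that("the enrichment score agrees with an independent implementation", {
    skip_if_not_installed("fgsea")
    set.seed(9)
    stats <- setNames(rnorm(300), paste0("g", 1:300))
    sel <- sample(names(stats), 25)
    mine <- isletAging:::.gseaES(sort(stats, decreasing = TRUE),
                                 names(sort(stats, decreasing = TRUE)) %in% sel)
    ref <- fgsea::calcGseaStat(sort(stats, decreasing = TRUE),
                               which(names(sort(stats, decreasing = TRUE))
                                     %in% sel),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-6)
})
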