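# Gene-set level statistics: set scores with group tests, per-gene group
# stats, fold-change matrices for curated lists, hypergeometric enrichment,
# and permutation GSEA for user-supplied sets.

#' Gene-set score and group test
#'
#' Per-cell score = mean log-normalized expression over the set genes present
#' in the matrix; groups are compared with a Welch two-tailed t-test. Used
#' for pathway panels such as the UPR branches (ATF6, IRE1, PERK), ERAD,
#' NRF2 or apoptosis gene lists.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param genes character vector (the gene set).
#' @param cellsA,cellsB cell ids of the two groups (A vs B, e.g. old vs
#'   young).
#' @param name label stored in the result.
#' @return a list with \code{set}, \code{genes_used}, \code{score} (named
#'   per-cell score over both groups), \code{mean_A}, \code{mean_B},
#'   \code{t}, \code{p}.
#' @export
genesetGroupTest <- function(sce, genes, cellsA, cellsB, name = "set") {
    used <- intersect(genes, rownames(sce))
    if (!length(used)) stop("gene set has no genes in the matrix")
    if (length(cellsA) < 2 || length(cellsB) < 2)
        stop("each group needs >= 2 cells")
    ln <- .getLogcounts(sce)[used, c(cellsA, cellsB), drop = FALSE]
    score <- colMeans(ln)
    a <- score[cellsA]
    b <- score[cellsB]
    if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) {
        tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
        tt <- t.test(a, b)
    }
    list(set = name, genes_used = used, score = score,
         mean_A = mean(a), mean_B = mean(b),
         t = unname(tt$statistic), p = tt$p.value)
}

#' Single-gene group statistics
#'
#' log2 fold change (difference of group means of log-normalized values, A
#' minus B) and Welch two-tailed t-test for one gene between two cell groups;
#' the workhorse behind single-gene aging marker panels (CDKN1A/CDKN2A,
#' IAPP, DDIT3, Bcl-2 family).
#'
#' @inheritParams genesetGroupTest
#' @param gene gene id.
#' @return a list with \code{gene}, \code{log2fc}, \code{t}, \code{p},
#'   \code{mean_A}, \code{mean_B}.
#' @export
geneGroupStats <- function(sce, gene, cellsA, cellsB) {
    if (!gene %in% rownames(sce)) stop("unknown gene: ", gene)
    res <- genesetGroupTest(sce, gene, cellsA, cellsB, name = gene)
    list(gene = gene, log2fc = res$mean_A - res$mean_B,
         t = res$t, p = res$p, mean_A = res$mean_A, mean_B = res$mean_B)
}

#' Old-versus-young fold-change matrix for a curated gene list
#'
#' For each cell type, computes the old-vs-young log2 fold change of every
#' listed gene, and masks the matrix to genes called differential in at least
#' one type under the standard DEG criteria (\code{\link{callDEGs}} on the
#' listed genes).
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts} and
#'   \code{age_group} in \code{colData}.
#' @param genes curated gene list (e.g. aging-database or SASP genes).
#' @param cellTypes types to include (default: all types present).
#' @param lfcMin,fdrMax mask thresholds (\code{\link{callDEGs}} defaults).
#' @param types optional per-cell type labels.
#' @return a genes x types matrix of log2 fold changes, containing only the
#'   genes differential in >= 1 type (possibly 0 rows).
#' @export
foldchangeMatrix <- function(sce, genes, cellTypes = NULL, lfcMin = 0.5,
                             fdrMax = 0.05, types = colData(sce)$cell_type) {
    genes <- intersect(genes, rownames(sce))
    if (!length(genes)) stop("no listed gene present in the matrix")
    if (is.null(cellTypes)) cellTypes <- sort(unique(types))
    age <- colData(sce)$age_group
    sub <- sce[genes, ]
    lfc <- matrix(NA_real_, length(genes), length(cellTypes),
                  dimnames = list(genes, cellTypes))
    pass <- matrix(FALSE, length(genes), length(cellTypes),
                   dimnames = list(genes, cellTypes))
    for (tp in cellTypes) {
        sel <- types == tp
        if (length(unique(age[sel])) < 2 || any(table(age[sel]) < 2))
            stop("cell type ", tp, " is missing an age group")
        tab <- callDEGs(sub, colnames(sub)[sel & age == "old"],
                        colnames(sub)[sel & age == "young"],
                        lfcMin = lfcMin, fdrMax = fdrMax, all = TRUE)
        lfc[tab$gene, tp] <- tab$log2fc
        pass[tab$gene, tp] <- abs(tab$log2fc) >= lfcMin & tab$fdr <= fdrMax
    }
    lfc[rowSums(pass) >= 1, , drop = FALSE]
}

#' One-sided hypergeometric enrichment of a hit list in a gene set
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between \code{hits} and \code{set} inside \code{universe}.
#'
#' @param hits,set character vectors, both subsets of \code{universe}.
#' @param universe the gene universe.
#' @return a list with \code{overlap}, \code{p} and the overlapping
#'   \code{genes}.
#' @examples
#' hypergeomEnrichment(letters[1:5], letters[1:5], letters[1:20])
#' @export
hypergeomEnrichment <- function(hits, set, universe) {
    hits <- unique(hits)
    set <- unique(set)
    universe <- unique(universe)
    if (!all(hits %in% universe) || !all(set %in% universe))
        stop("hits and set must be subsets of the universe")
    k <- length(intersect(hits, set))
    p <- phyper(k - 1, length(set), length(universe) - length(set),
                length(hits), lower.tail = FALSE)
    list(overlap = k, p = p, genes = intersect(hits, set))
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score (weight exponent
# 1). stats must be sorted decreasingly; inSet logical along that order.
.gseaES <- function(statsSorted, inSet) {
    nh <- sum(inSet)
    if (nh == 0 || nh == length(inSet)) stop("set must be a proper subset")
    w <- abs(statsSorted)
    stepHit <- ifelse(inSet, w / sum(w[inSet]), 0)
    if (sum(w[inSet]) == 0) stepHit[inSet] <- 1 / nh
    stepMiss <- ifelse(inSet, 0, 1 / (length(inSet) - nh))
    running <- cumsum(stepHit - stepMiss)
    i <- which.max(abs(running))
    running[i]
}

#' Gene set enrichment analysis with a gene-permutation null
#'
#' Genes are ranked by a signed score (typically the old-vs-young log2 fold
#' change of a group contrast); the enrichment score (ES) is the extremum of
#' the weighted Kolmogorov-Smirnov running sum (hit weight proportional to
#' |score|). The null is built by permuting gene labels (drawing random sets
#' of the same size), which keeps the procedure deterministic and cheap at
#' desk scale; the normalized enrichment score (NES) is the ES divided by the
#' mean |null ES| of the same sign, and the nominal p-value is the add-one
#' empirical tail probability among same-sign null ES values. FDR q-values
#' are Benjamini-Hochberg across the tested sets.
#'
#' @param stats named numeric vector of per-gene ranking scores.
#' @param geneSets named list of character vectors.
#' @param nPerm permutations per set (default 1000).
#' @param seed integer seed.
#' @return a data.frame (\code{set}, \code{size}, \code{ES}, \code{NES},
#'   \code{p}, \code{q}) for the sets with a non-empty intersection with the
#'   ranking; sets without one raise an error if none remain.
#' @export
gseaTest <- function(stats, geneSets, nPerm = 1000L, seed = 0L) {
    if (is.null(names(stats))) stop("stats must be a named vector")
    ord <- order(stats, decreasing = TRUE)
    s <- stats[ord]
    genes <- names(s)
    rows <- lapply(names(geneSets), function(nm) {
        size <- sum(genes %in% geneSets[[nm]])
        if (size == 0 || size == length(genes)) return(NULL)
        inSet <- genes %in% geneSets[[nm]]
        es <- .gseaES(s, inSet)
        nullES <- .withSeed(seed + match(nm, names(geneSets)), {
            vapply(seq_len(nPerm), function(i) {
                idx <- sample.int(length(genes), size)
                flag <- logical(length(genes))
                flag[idx] <- TRUE
                .gseaES(s, flag)
            }, 0)
        })
        same <- nullES[sign(nullES) == sign(es) | nullES == 0]
        if (!length(same)) same <- 0
        nes <- es / mean(abs(same))
        p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
        data.frame(set = nm, size = size, ES = es, NES = nes, p = p)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) stop("no gene set intersects the ranking")
    res <- do.call(rbind, rows)
    res$q <- adjustFDR(res$p)
    res[order(-abs(res$NES)), , drop = FALSE]
}
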