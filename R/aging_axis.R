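# PCA-based aging axis: find the principal component separating young from
# old cells consistently across donors, define young-like/old-like states,
# and call aging-associated DEGs.

#' Principal component analysis of one cell population
#'
#' Genes are centered and, by default, unit-scaled before a truncated PCA.
#' Zero-variance genes are dropped. The loading sign is fixed so the
#' largest-magnitude loading is positive (determinism).
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param cells cell ids (or logical/integer index) selecting one population.
#' @param nComponents number of components (default 10).
#' @param scale unit-scale genes before decomposition (default TRUE).
#' @param seed seed for the truncated SVD initialisation.
#' @param nTopGenes optionally restrict the decomposition to the genes with
#'   the largest excess variance over the mean-variance trend (highly
#'   variable genes). The default \code{NULL} uses all non-constant genes,
#'   which proved the more reliable choice for donor-consistent axis
#'   discovery on overdispersed counts; see the package vignette.
#' @return a list with \code{scores} (cells x components), \code{loadings}
#'   (genes x components, orthonormal), \code{varianceExplained} and
#'   \code{genes} (the genes retained).
#' @export
fitPCA <- function(sce, cells = colnames(sce), nComponents = 10L,
                   scale = TRUE, seed = 0L, nTopGenes = NULL) {
    X <- t(.getLogcounts(sce)[, cells, drop = FALSE])
    if (nrow(X) < nComponents)
        stop("need at least n_components cells")
    .pcaScores(X, nComponents, scale = scale, seed = seed,
               nTopGenes = nTopGenes)
}

#' Select the age-separating principal component
#'
#' Every component up to \code{maxPC} is oriented so that the mean score of
#' old cells exceeds that of young cells, then scored by the cell-level AUC
#' (old versus young). A component is donor-consistent when every donor's
#' median score falls on its own age group's side of the midpoint between the
#' two group medians; donor medians are the unit of evidence because age is
#' constant within donor, so cell-level separation alone could reflect a
#' single donor's batch shift. Among fully consistent components the one with
#' the highest AUC is selected; \code{NULL} is returned when none is fully
#' consistent (the population is not discriminated by this method).
#'
#' @param pca result of \code{\link{fitPCA}}.
#' @param meta data.frame with \code{cell_id}, \code{donor_id},
#'   \code{age_group} for the same cells (e.g. \code{colData} subset).
#' @param cellType label stored in the result (default "unknown").
#' @param maxPC number of leading components scanned (default all fitted).
#' @return an \code{\linkS4class{AgingAxis}} or \code{NULL}.
#' @export
selectAgePC <- function(pca, meta, cellType = "unknown",
                        maxPC = ncol(pca$scores)) {
    scores <- pca$scores
    meta <- as.data.frame(meta)
    meta <- meta[match(rownames(scores), meta$cell_id), , drop = FALSE]
    isOld <- meta$age_group == "old"
    if (!any(isOld) || all(isOld)) stop("need both age groups")
    donorsPerGroup <- table(unique(meta[, c("donor_id", "age_group")])$age_group)
    if (any(donorsPerGroup < 2))
        warning("a group has a single donor; donor consistency is degenerate")

    maxPC <- min(maxPC, ncol(scores))
    best <- NULL
    for (j in seq_len(maxPC)) {
        s <- scores[, j]
        orient <- if (mean(s[isOld]) >= mean(s[!isOld])) 1 else -1
        s <- orient * s
        auc <- rankAUC(s, isOld)
        medOld <- median(s[isOld])
        medYoung <- median(s[!isOld])
        mid <- (medOld + medYoung) / 2
        dm <- aggregate(list(median_score = s),
                        by = list(donor_id = meta$donor_id,
                                  age_group = meta$age_group),
                        FUN = median)
        dm$consistent <- ifelse(dm$age_group == "old",
                                dm$median_score > mid,
                                dm$median_score < mid)
        if (all(dm$consistent) && (is.null(best) || auc > best@auc)) {
            best <- new("AgingAxis", cellType = cellType, pcIndex = j,
                        orientation = orient,
                        scores = setNames(s, rownames(scores)),
                        auc = auc, donorMedians = dm,
                        loading = setNames(orient * pca$loadings[, j],
                                           rownames(pca$loadings)),
                        midpoint = mid)
        }
    }
    best
}

#' Assign young-like and old-like cell states along an aging axis
#'
#' The midpoint between the old and young group median scores is the
#' threshold: cells of old donors above it are \code{old-like}, cells of
#' young donors below it are \code{young-like}, and every other cell is
#' \code{excluded}. By construction no cell is assigned against its donor's
#' age group.
#'
#' @param axis an \code{\linkS4class{AgingAxis}}.
#' @param meta data.frame with \code{cell_id}, \code{age_group} covering the
#'   scored cells.
#' @return a data.frame (\code{cell_id}, \code{state}).
#' @export
assignAgeStates <- function(axis, meta) {
    meta <- as.data.frame(meta)
    s <- axisScores(axis)
    age <- meta$age_group[match(names(s), meta$cell_id)]
    state <- rep("excluded", length(s))
    state[age == "old" & s > axis@midpoint] <- "old-like"
    state[age == "young" & s < axis@midpoint] <- "young-like"
    data.frame(cell_id = names(s), state = state, row.names = NULL)
}

#' Differentially expressed genes between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on log-normalized values, with
#' log2 fold change computed as the difference of group means (A minus B) and
#' Benjamini-Hochberg FDR across genes. Genes pass when |log2FC| >=
#' \code{lfcMin} and FDR <= \code{fdrMax}.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param cellsA,cellsB cell ids of the two groups (A is the "old-like" /
#'   numerator side).
#' @param lfcMin,fdrMax filter thresholds (defaults 0.5 and 0.05).
#' @param all return all genes (unfiltered) when TRUE.
#' @return a data.frame (\code{gene}, \code{log2fc}, \code{p}, \code{fdr},
#'   \code{direction}) with direction \code{up} iff log2FC > 0, sorted by
#'   decreasing |log2FC|.
#' @export
callDEGs <- function(sce, cellsA, cellsB, lfcMin = 0.5, fdrMax = 0.05,
                     all = FALSE) {
    idxA <- match(cellsA, colnames(sce))
    idxB <- match(cellsB, colnames(sce))
    if (anyNA(idxA) || anyNA(idxB)) stop("unknown cell ids")
    if (length(idxA) < 2 || length(idxB) < 2)
        stop("each group needs >= 2 cells")
    ln <- .getLogcounts(sce)
    w <- rowWilcoxon(ln, idxA, idxB)
    res <- data.frame(gene = rownames(sce),
                      log2fc = unname(log2FCMeans(ln, idxA, idxB)),
                      p = w$p, fdr = adjustFDR(w$p), row.names = NULL)
    res$direction <- ifelse(res$log2fc > 0, "up", "down")
    if (!all)
        res <- res[abs(res$log2fc) >= lfcMin & res$fdr <= fdrMax, ,
                   drop = FALSE]
    res[order(-abs(res$log2fc)), , drop = FALSE]
}

#' Aging axis pipeline for one cell type
#'
#' Convenience wrapper: fit a PCA on the type's cells, select the
#' age-separating component, assign young-like/old-like states, and call
#' aging-associated DEGs (old-like versus young-like).
#'
#' @inheritParams fitPCA
#' @param sce a \code{SingleCellExperiment} with \code{logcounts} and
#'   \code{donor_id}/\code{age_group} in \code{colData}.
#' @param cellType the type to analyse.
#' @param maxPC components scanned (default 10).
#' @param lfcMin,fdrMax DEG thresholds.
#' @param types optional per-cell type labels overriding
#'   \code{colData(sce)$cell_type}.
#' @return a list with \code{axis} (\code{AgingAxis} or NULL),
#'   \code{assignment} and \code{degs} (NULL when no axis was found).
#' @export
agingAxisDEGs <- function(sce, cellType, maxPC = 10L, nComponents = maxPC,
                          scale = TRUE, seed = 0L, lfcMin = 0.5,
                          fdrMax = 0.05, nTopGenes = NULL,
                          types = colData(sce)$cell_type) {
    cells <- colnames(sce)[types == cellType]
    meta <- as.data.frame(colData(sce)[cells, , drop = FALSE])
    pca <- fitPCA(sce, cells, nComponents = nComponents, scale = scale,
                  seed = seed, nTopGenes = nTopGenes)
    axis <- selectAgePC(pca, meta, cellType = cellType, maxPC = maxPC)
    if (is.null(axis))
        return(list(axis = NULL, assignment = NULL, degs = NULL))
    assignment <- assignAgeStates(axis, meta)
    degs <- callDEGs(sce,
                     assignment$cell_id[assignment$state == "old-like"],
                     assignment$cell_id[assignment$state == "young-like"],
                     lfcMin = lfcMin, fdrMax = fdrMax)
    list(axis = axis, assignment = assignment, degs = degs)
}

#' Direct young-versus-old differential expression for one cell type
#'
#' The cross-check to the axis-based procedure: the same test applied to all
#' old cells against all young cells of the type, regardless of axis scores.
#'
#' @inheritParams agingAxisDEGs
#' @return a DEG data.frame as in \code{\link{callDEGs}} (old vs young).
#' @export
directDEGs <- function(sce, cellType, lfcMin = 0.5, fdrMax = 0.05,
                       types = colData(sce)$cell_type) {
    sel <- types == cellType
    age <- colData(sce)$age_group
    callDEGs(sce, colnames(sce)[sel & age == "old"],
             colnames(sce)[sel & age == "young"],
             lfcMin = lfcMin, fdrMax = fdrMax)
}

#' Sex-stratified aging-associated DEGs
#'
#' Runs the full axis -> assignment -> DEG pipeline separately within each
#' sex and reports the per-stratum DEG tables together with the overlap of
#' their upregulated and downregulated gene sets. A stratum missing an age
#' group (or failing to yield an axis) is skipped with a warning.
#'
#' @inheritParams agingAxisDEGs
#' @return a list with \code{per_stratum} (named list of
#'   \code{\link{agingAxisDEGs}} results), \code{overlap_up} and
#'   \code{overlap_down} (see \code{\link{overlapSets}}; NULL when fewer than
#'   two strata produced DEGs).
#' @export
stratifiedDEGs <- function(sce, cellType, maxPC = 10L, scale = TRUE,
                           seed = 0L, lfcMin = 0.5, fdrMax = 0.05,
                           nTopGenes = NULL,
                           types = colData(sce)$cell_type) {
    meta <- colData(sce)
    out <- list()
    for (sx in sort(unique(meta$sex))) {
        keep <- meta$sex == sx
        sub <- sce[, keep]
        subTypes <- types[keep]
        ageTab <- table(meta$age_group[keep & types == cellType])
        if (length(ageTab) < 2 || any(ageTab < 2)) {
            warning("stratum ", sx, " lacks an age group for ", cellType,
                    "; skipped")
            next
        }
        res <- agingAxisDEGs(sub, cellType, maxPC = maxPC, scale = scale,
                             seed = seed, lfcMin = lfcMin, fdrMax = fdrMax,
                             nTopGenes = nTopGenes, types = subTypes)
        if (is.null(res$axis)) {
            warning("no consistent aging axis in stratum ", sx, " for ",
                    cellType)
            next
        }
        out[[sx]] <- res
    }
    if (length(out) < 2)
        warning("fewer than two strata produced DEG tables; ",
                "no overlap computed")
    up <- lapply(out, function(r) r$degs$gene[r$degs$direction == "up"])
    down <- lapply(out, function(r) r$degs$gene[r$degs$direction == "down"])
    list(per_stratum = out,
         overlap_up = if (length(up) >= 2) overlapSets(up[[1]], up[[2]]) else NULL,
         overlap_down = if (length(down) >= 2)
             overlapSets(down[[1]], down[[2]]) else NULL)
}
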