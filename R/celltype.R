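# Clustering, marker-based endocrine type annotation, and per-type marker
# gene discovery.

# PCA helper shared by clustering and the aging axis. X: cells x genes.
# Drops zero-variance genes before optional unit scaling. Uses a truncated
# SVD (irlba) when the problem is large, exact prcomp otherwise.
.pcaScores <- function(X, nComponents, scale = TRUE, seed = 0L,
                       nTopGenes = NULL) {
    sds <- .colSds(X)
    keep <- sds > 0
    if (!is.null(nTopGenes) && sum(keep) > nTopGenes) {
        # highly variable genes: excess variance above the mean-variance
        # trend, so selection favours genuine biological structure rather
        # than the count-noise ceiling of highly expressed genes
        excess <- .excessVariance(colMeans(X), sds^2)
        thr <- sort(excess[keep], decreasing = TRUE)[nTopGenes]
        keep <- keep & excess >= thr
    }
    X <- X[, keep, drop = FALSE]
    if (nComponents > min(dim(X)))
        stop("n_components exceeds the matrix rank bound")
    Xs <- base::scale(X, center = TRUE, scale = scale)
    big <- min(dim(Xs)) > max(100L, 4L * nComponents)
    if (big) {
        pc <- .withSeed(seed, irlba::prcomp_irlba(Xs, n = nComponents,
                                                  center = FALSE,
                                                  scale. = FALSE))
        scores <- pc$x
        rotation <- pc$rotation
        sdev <- pc$sdev
        totVar <- sum(.colSds(Xs)^2)
    } else {
        pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
        scores <- pc$x[, seq_len(nComponents), drop = FALSE]
        rotation <- pc$rotation[, seq_len(nComponents), drop = FALSE]
        sdev <- pc$sdev[seq_len(nComponents)]
        totVar <- sum(pc$sdev^2)
    }
    rownames(scores) <- rownames(X)
    rownames(rotation) <- colnames(X)
    # deterministic sign convention: largest-magnitude loading positive
    for (j in seq_len(ncol(rotation))) {
        i <- which.max(abs(rotation[, j]))
        if (rotation[i, j] < 0) {
            rotation[, j] <- -rotation[, j]
            scores[, j] <- -scores[, j]
        }
    }
    list(scores = scores, loadings = rotation,
         varianceExplained = sdev^2 / totVar, genes = colnames(X))
}

# per-gene variance in excess of a loess mean-variance trend
.excessVariance <- function(mu, v) {
    fit <- tryCatch(stats::loess(v ~ mu, degree = 1, span = 0.3,
                                 family = "symmetric"),
                    error = function(e) NULL)
    if (is.null(fit)) return(v)
    v - stats::fitted(fit)
}

# colSds without importing matrixStats (kept dependency-light); exact.
.colSds <- function(X) {
    n <- nrow(X)
    if (n < 2) return(rep(0, ncol(X)))
    mu <- colMeans(X)
    sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1))
}

#' Cluster cells in principal-component space
#'
#' Cells are embedded in the leading principal components of the most
#' variable genes and partitioned by k-means, with the number of clusters
#' chosen automatically as the partition maximizing the mean silhouette
#' width over \code{2:kMax}. The number of clusters is therefore not fixed
#' in advance. Restricting to a handful of leading components matters: the
#' discrete cell-type structure lives there, and deeper components add
#' isotropic noise that degrades both the partition and its model selection.
#' Deterministic given \code{seed}.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param nPCs number of principal components (default 5).
#' @param kMax largest number of clusters considered (default 8).
#' @param nTopGenes number of highly variable genes (largest excess variance
#'   over the mean-variance trend) fed to the PCA (default 1000); cell-type
#'   structure lives in a small set of strongly variable markers, which a
#'   whole-transcriptome decomposition would dilute.
#' @param seed integer seed (SVD initialisation, k-means starts, silhouette
#'   subsampling).
#' @return a data.frame (\code{cell_id}, \code{cluster}) with cluster labels
#'   contiguous from 0, ordered by decreasing cluster size; parameters and the
#'   silhouette profile are attached as attributes.
#' @export
clusterCells <- function(sce, nPCs = 5L, kMax = 8L, nTopGenes = 1000L,
                         seed = 0L) {
    n <- ncol(sce)
    if (n < 4) stop("need at least 4 cells")
    X <- t(.getLogcounts(sce))
    pca <- .pcaScores(X, nPCs, scale = TRUE, seed = seed,
                      nTopGenes = nTopGenes)
    sc <- pca$scores
    ks <- seq(2L, min(kMax, n - 1L))
    sel <- .withSeed(seed + 1L, {
        sub <- if (n > 1500) sample(n, 1500) else seq_len(n)
        D <- dist(sc[sub, , drop = FALSE])
        fits <- lapply(ks, function(k)
            stats::kmeans(sc, k, nstart = 25, iter.max = 100))
        sil <- vapply(fits, function(f)
            mean(cluster::silhouette(f$cluster[sub], D)[, 3]), 0)
        list(fit = fits[[which.max(sil)]], sil = setNames(sil, ks))
    })
    member <- sel$fit$cluster
    # relabel 0-based by decreasing size; ties broken by lowest cell index
    sizes <- table(member)
    firstIdx <- vapply(names(sizes), function(l) min(which(member == l)), 0)
    ord <- names(sizes)[order(-sizes, firstIdx)]
    cluster <- match(as.character(member), ord) - 1L
    out <- data.frame(cell_id = colnames(sce), cluster = cluster)
    attr(out, "n_pcs") <- nPCs
    attr(out, "k_max") <- kMax
    attr(out, "silhouette") <- sel$sil
    attr(out, "seed") <- seed
    out
}

#' Annotate clusters with endocrine cell types from canonical markers
#'
#' For every marker gene the cluster means of log-normalized expression are
#' z-scored across clusters (removing the scale differences between
#' hormones); each cluster receives the cell type whose markers have the
#' highest average z-score. A winning margin below \code{tieMargin} yields
#' \code{"unassigned"}.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param clusters data.frame from \code{\link{clusterCells}}.
#' @param markerSpec data.frame with columns \code{gene}, \code{cell_type},
#'   e.g. GCG = alpha, INS = beta, SST = delta, PPY = PP.
#' @param tieMargin minimum z-score margin between the best and second-best
#'   type (default 0.1).
#' @return a data.frame (\code{cell_id}, \code{cluster}, \code{cell_type}).
#' @export
annotateTypes <- function(sce, clusters, markerSpec, tieMargin = 0.1) {
    absent <- setdiff(markerSpec$gene, rownames(sce))
    if (length(absent))
        stop("marker gene(s) absent from matrix: ",
             paste(absent, collapse = ", "))
    ln <- .getLogcounts(sce)[markerSpec$gene, , drop = FALSE]
    cl <- clusters$cluster[match(colnames(sce), clusters$cell_id)]
    clLevels <- sort(unique(cl))
    means <- vapply(clLevels, function(k)
        rowMeans(ln[, cl == k, drop = FALSE]), numeric(nrow(ln)))
    means <- matrix(means, nrow = nrow(ln),
                    dimnames = list(markerSpec$gene, clLevels))
    z <- t(base::scale(t(means)))      # z across clusters, per marker
    z[is.nan(z)] <- 0                  # marker flat across clusters
    typeZ <- rowsum(z, group = markerSpec$cell_type) /
        as.vector(table(markerSpec$cell_type)[sort(unique(markerSpec$cell_type))])
    assignCluster <- apply(typeZ, 2L, function(v) {
        o <- order(v, decreasing = TRUE)
        if (length(v) > 1 && v[o[1]] - v[o[2]] < tieMargin) "unassigned"
        else rownames(typeZ)[o[1]]
    })
    names(assignCluster) <- colnames(typeZ)
    data.frame(cell_id = clusters$cell_id,
               cluster = clusters$cluster,
               cell_type = unname(assignCluster[as.character(clusters$cluster)]))
}

#' Cell-type-specific marker genes (one-vs-rest Wilcoxon)
#'
#' For every cell type, each gene is tested with a two-sided Wilcoxon
#' rank-sum test of that type's cells against all remaining cells on
#' log-normalized values, with Benjamini-Hochberg FDR within type. Genes are
#' reported when log2FC >= \code{lfcMin}, FDR <= \code{fdrMax} and the gene
#' is detected in at least \code{fracMin} of the type's cells.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param types named character vector or data.frame column of per-cell type
#'   labels, aligned with \code{colnames(sce)}; or a data.frame from
#'   \code{\link{annotateTypes}}.
#' @param lfcMin,fdrMax,fracMin filter thresholds (defaults 0.5, 0.05, 0.25).
#' @return a data.frame (\code{gene}, \code{cell_type}, \code{log2fc},
#'   \code{p}, \code{fdr}, \code{fraction_in}, \code{fraction_out}), sorted by
#'   decreasing log2FC within type.
#' @export
findTypeMarkers <- function(sce, types, lfcMin = 0.5, fdrMax = 0.05,
                            fracMin = 0.25) {
    if (is.data.frame(types))
        types <- setNames(types$cell_type, types$cell_id)[colnames(sce)]
    types <- as.character(types)
    tab <- table(types)
    if (sum(tab >= 2) < 2) stop("need >= 2 types with >= 2 cells each")
    ln <- .getLogcounts(sce)
    pos <- counts(sce) > 0
    out <- lapply(names(tab)[tab >= 2], function(tp) {
        idxA <- which(types == tp)
        idxB <- which(types != tp)
        if (length(idxB) < 2) return(NULL)
        w <- rowWilcoxon(ln, idxA, idxB)
        lfc <- log2FCMeans(ln, idxA, idxB)
        data.frame(gene = rownames(sce), cell_type = tp,
                   log2fc = unname(lfc), p = w$p, fdr = adjustFDR(w$p),
                   fraction_in = rowMeans(pos[, idxA, drop = FALSE]),
                   fraction_out = rowMeans(pos[, idxB, drop = FALSE]),
                   row.names = NULL)
    })
    res <- do.call(rbind, out)
    res <- res[res$log2fc >= lfcMin & res$fdr <= fdrMax &
               res$fraction_in >= fracMin, , drop = FALSE]
    res[order(res$cell_type, -res$log2fc), , drop = FALSE]
}
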