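# Regulator -> target network over aging-associated DEGs and hub ranking.

#' Infer a regulator-target network by rank correlation
#'
#' The weight of a candidate edge regulator -> target is the absolute
#' Spearman correlation of their log-normalized expression across the
#' analysed cells (invariant under monotone transforms, robust to the
#' mean-variance trend of counts). Edges whose weight exceeds the
#' \code{weightQuantile} quantile of all candidate weights are retained.
#' Constant genes yield weight 0. Self-edges (regulator = target) are never
#' candidates.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param regulators,targets gene ids (may overlap).
#' @param cells cells to analyse (default all).
#' @param weightQuantile retention quantile over candidate weights
#'   (default 0.90).
#' @return a data.frame (\code{regulator}, \code{target}, \code{weight}),
#'   sorted by decreasing weight, with the threshold as an attribute.
#' @export
inferNetwork <- function(sce, regulators, targets, cells = colnames(sce),
                         weightQuantile = 0.90) {
    missing <- setdiff(unique(c(regulators, targets)), rownames(sce))
    if (length(missing))
        stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    ln <- .getLogcounts(sce)[, cells, drop = FALSE]
    R <- t(ln[unique(regulators), , drop = FALSE])
    T_ <- t(ln[unique(targets), , drop = FALSE])
    W <- abs(suppressWarnings(cor(R, T_, method = "spearman")))
    W[is.na(W)] <- 0
    grid <- expand.grid(regulator = colnames(R), target = colnames(T_),
                        stringsAsFactors = FALSE)
    grid$weight <- W[cbind(grid$regulator, grid$target)]
    grid <- grid[grid$regulator != grid$target, , drop = FALSE]
    thr <- quantile(grid$weight, weightQuantile, names = FALSE)
    edges <- grid[grid$weight > thr, , drop = FALSE]
    edges <- edges[order(-edges$weight), , drop = FALSE]
    rownames(edges) <- NULL
    attr(edges, "threshold") <- thr
    attr(edges, "n_candidates") <- nrow(grid)
    edges
}

#' Rank hub regulators by out-degree
#'
#' Regulators are ranked by the number of retained edges, with ties broken by
#' total edge weight and then lexically, making the ranking deterministic.
#'
#' @param edges data.frame from \code{\link{inferNetwork}}.
#' @return a data.frame (\code{regulator}, \code{degree}, \code{total_weight})
#'   in rank order (possibly 0 rows).
#' @export
hubRanking <- function(edges) {
    if (!nrow(edges))
        return(data.frame(regulator = character(), degree = integer(),
                          total_weight = numeric()))
    agg <- aggregate(list(total_weight = edges$weight),
                     by = list(regulator = edges$regulator), FUN = sum)
    agg$degree <- as.vector(table(edges$regulator)[agg$regulator])
    agg <- agg[order(-agg$degree, -agg$total_weight, agg$regulator), ,
               drop = FALSE]
    rownames(agg) <- NULL
    agg[, c("regulator", "degree", "total_weight")]
}
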