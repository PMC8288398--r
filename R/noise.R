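# Cell-to-cell transcriptional noise: per-cell deviation from the mean
# profile of its (cell type, age group), compared between age groups.

#' Per-cell transcriptional noise
#'
#' For one cell type, restricts to genes detected in at least \code{fracMin}
#' of that type's cells, computes the mean log-normalized profile (centroid)
#' separately per age group, and scores each cell by its distance to its own
#' group's centroid. Centroids are per (type, age group) so that mean aging
#' shifts in expression do not masquerade as noise; the statistic isolates
#' dispersion around the group mean. The Euclidean distance is divided by the
#' square root of the number of genes used, making the scale stable under
#' changes of the gene subset; a \code{"pearson"} metric (1 - correlation to
#' the centroid) is available as an alternative.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts} and
#'   \code{age_group} in \code{colData}.
#' @param cellType cell type to analyse (matched against
#'   \code{colData(sce)$cell_type} unless \code{types} is given).
#' @param fracMin minimum detection fraction for a gene to enter the
#'   statistic (default 0.1).
#' @param metric \code{"euclidean"} (default) or \code{"pearson"}.
#' @param types optional per-cell type labels overriding
#'   \code{colData(sce)$cell_type}.
#' @return a data.frame (\code{cell_id}, \code{donor_id}, \code{age_group},
#'   \code{noise}) for the cells of the type, with the gene subset and
#'   parameters attached as attributes.
#' @export
transcriptionalNoise <- function(sce, cellType, fracMin = 0.1,
                                 metric = c("euclidean", "pearson"),
                                 types = colData(sce)$cell_type) {
    metric <- match.arg(metric)
    sel <- which(types == cellType)
    if (length(sel) < 4) stop("too few cells of type ", cellType)
    meta <- colData(sce)[sel, , drop = FALSE]
    if (any(table(meta$age_group) < 2))
        stop("each age group needs >= 2 cells of type ", cellType)
    ln <- .getLogcounts(sce)[, sel, drop = FALSE]
    genes <- rownames(sce)[rowMeans(counts(sce)[, sel, drop = FALSE] > 0) >=
                           fracMin]
    if (!length(genes)) stop("empty gene subset at fracMin = ", fracMin)
    ln <- ln[genes, , drop = FALSE]

    noise <- numeric(length(sel))
    for (grp in unique(meta$age_group)) {
        idx <- which(meta$age_group == grp)
        centroid <- rowMeans(ln[, idx, drop = FALSE])
        dev <- ln[, idx, drop = FALSE] - centroid
        noise[idx] <- if (metric == "euclidean")
            sqrt(colSums(dev^2)) / sqrt(length(genes))
        else
            1 - suppressWarnings(cor(ln[, idx, drop = FALSE], centroid))[, 1]
    }
    out <- data.frame(cell_id = colnames(ln),
                      donor_id = meta$donor_id,
                      age_group = meta$age_group,
                      noise = noise)
    attr(out, "genes") <- genes
    attr(out, "cell_type") <- cellType
    attr(out, "frac_min") <- fracMin
    attr(out, "metric") <- metric
    out
}

#' Old-versus-young test of transcriptional noise
#'
#' Welch two-sample two-tailed t-test of per-cell noise, old against young.
#'
#' @param noise data.frame from \code{\link{transcriptionalNoise}}.
#' @return a list with \code{t}, \code{p}, \code{mean_old}, \code{mean_young},
#'   \code{n_old}, \code{n_young} and the analysed \code{cell_type}.
#' @export
compareNoise <- function(noise) {
    old <- noise$noise[noise$age_group == "old"]
    young <- noise$noise[noise$age_group == "young"]
    if (length(old) < 2 || length(young) < 2)
        stop("both age groups need >= 2 cells")
    tt <- t.test(old, young)
    list(cell_type = attr(noise, "cell_type"),
         t = unname(tt$statistic), p = tt$p.value,
         mean_old = mean(old), mean_young = mean(young),
         n_old = length(old), n_young = length(young))
}

#' Genes whose expression tracks transcriptional noise
#'
#' Pearson correlation of each gene's log-normalized expression with the
#' per-cell noise statistic across the analysed cells, with two-sided
#' p-values and Benjamini-Hochberg FDR. A gene passes when its correlation
#' exceeds \code{rMin} (positive correlations only) and its FDR is at most
#' \code{fdrMax}. Genes constant across the cells have undefined correlation
#' and are reported with \code{NA} and \code{passes = FALSE}.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param noise data.frame from \code{\link{transcriptionalNoise}}.
#' @param rMin correlation threshold (default 0.6).
#' @param fdrMax FDR threshold (default 0.05).
#' @return a data.frame (\code{gene}, \code{r}, \code{p}, \code{fdr},
#'   \code{passes}).
#' @export
noiseCorrelatedGenes <- function(sce, noise, rMin = 0.6, fdrMax = 0.05) {
    cells <- noise$cell_id
    if (!all(cells %in% colnames(sce)))
        stop("noise vector refers to cells absent from the matrix")
    ln <- .getLogcounts(sce)[, cells, drop = FALSE]
    cp <- rowPearson(ln, noise$noise)
    fdr <- adjustFDR(cp$p)
    passes <- !is.na(cp$r) & cp$r > rMin & fdr <= fdrMax
    data.frame(gene = rownames(sce), r = cp$r, p = cp$p, fdr = fdr,
               passes = passes, row.names = NULL)
}

#' Bin cells by transcriptional noise rank
#'
#' Within each age group, cells are ranked by noise and split into
#' \code{nBins} nearly equal bins (sizes differ by at most one; earlier bins
#' take the remainder). Bins are a display device for noise-ordered heatmaps.
#'
#' @param noise data.frame from \code{\link{transcriptionalNoise}}.
#' @param nBins number of bins per age group.
#' @return a data.frame (\code{cell_id}, \code{age_group}, \code{bin}) with
#'   bins numbered from 1 (lowest noise) within each group.
#' @export
binCellsByNoise <- function(noise, nBins) {
    if (nBins < 1) stop("n_bins must be >= 1")
    out <- lapply(split(noise, noise$age_group), function(df) {
        n <- nrow(df)
        if (nBins > n) stop("n_bins exceeds the number of cells in a group")
        sizes <- n %/% nBins + (seq_len(nBins) <= n %% nBins)
        ord <- order(df$noise)
        bin <- integer(n)
        bin[ord] <- rep(seq_len(nBins), times = sizes)
        data.frame(cell_id = df$cell_id, age_group = df$age_group, bin = bin)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
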