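# Ligand-receptor interaction scoring between cell types with an empirical
# cell-type-label permutation test.

.typeMeans <- function(M, labels) {
    # rows = genes; returns genes x types mean matrix
    g <- rowsum(t(M), group = labels)
    t(g / as.vector(table(labels)[rownames(g)]))
}

#' Score one ligand-receptor pair between two cell types
#'
#' The interaction score is the arithmetic mean of the ligand's mean
#' log-normalized expression in the sender type and the receptor's mean in
#' the receiver type. The pair is tested only when the ligand is detected in
#' at least \code{fracMin} of sender cells and the receptor in at least
#' \code{fracMin} of receiver cells.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param ligand,receptor gene ids.
#' @param sender,receiver cell type labels.
#' @param fracMin expression-fraction filter (default 0.1).
#' @param types optional per-cell type labels.
#' @return a list with \code{score} (NA when untested), \code{tested} and
#'   \code{reason} (why a pair was not tested).
#' @export
lrScore <- function(sce, ligand, receptor, sender, receiver, fracMin = 0.1,
                    types = colData(sce)$cell_type) {
    for (g in c(ligand, receptor))
        if (!g %in% rownames(sce)) stop("unknown gene: ", g)
    for (tp in c(sender, receiver))
        if (!tp %in% types) stop("unknown cell type: ", tp)
    sCells <- colnames(sce)[types == sender]
    rCells <- colnames(sce)[types == receiver]
    fracL <- expressionFraction(sce, ligand, sCells)
    fracR <- expressionFraction(sce, receptor, rCells)
    if (fracL < fracMin || fracR < fracMin) {
        reason <- sprintf(
            "expression fraction below %.2f (ligand %.2f in %s, receptor %.2f in %s)",
            fracMin, fracL, sender, fracR, receiver)
        return(list(score = NA_real_, tested = FALSE, reason = reason))
    }
    ln <- .getLogcounts(sce)
    score <- (mean(ln[ligand, sCells]) + mean(ln[receptor, rCells])) / 2
    list(score = score, tested = TRUE, reason = NA_character_)
}

#' Permutation test of ligand-receptor interactions across cell-type pairs
#'
#' For every ordered (sender, receiver) type combination and every pair in
#' \code{pairs}, the observed score of \code{\link{lrScore}} is compared to a
#' null built by shuffling the cell-type labels across cells \code{nPerm}
#' times. One shared shuffle sequence is used for all pairs within an
#' iteration (shuffles permute labels, preserving type sizes exactly). The
#' empirical p-value is \code{(1 + #(null >= observed)) / (nPerm + 1)}, so it
#' respects the add-one floor \code{1/(nPerm + 1)}. Pairs failing the
#' expression-fraction filter (evaluated on the observed labels) are reported
#' untested with a reason.
#'
#' @param sce a \code{SingleCellExperiment} with \code{logcounts}.
#' @param pairs data.frame with columns \code{ligand}, \code{receptor}.
#' @param nPerm number of label permutations (default 500).
#' @param fracMin expression-fraction filter (default 0.1).
#' @param seed integer seed for the shuffle sequence.
#' @param types optional per-cell type labels.
#' @return a data.frame (\code{sender}, \code{receiver}, \code{ligand},
#'   \code{receptor}, \code{mean_score}, \code{p}, \code{tested},
#'   \code{reason}).
#' @export
lrPermutationTest <- function(sce, pairs, nPerm = 500L, fracMin = 0.1,
                              seed = 0L, types = colData(sce)$cell_type) {
    if (nPerm < 1) stop("n_perm must be >= 1")
    pairs <- unique(pairs[, c("ligand", "receptor")])
    missing <- setdiff(unique(c(pairs$ligand, pairs$receptor)), rownames(sce))
    if (length(missing))
        stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    typeLevels <- sort(unique(types))
    if (length(typeLevels) < 2) stop("need >= 2 cell types")

    genes <- unique(c(pairs$ligand, pairs$receptor))
    M <- .getLogcounts(sce)[genes, , drop = FALSE]
    det <- counts(sce)[genes, , drop = FALSE] > 0

    obsMeans <- .typeMeans(M, types)[, typeLevels, drop = FALSE]
    detFrac <- .typeMeans(det * 1, types)[, typeLevels, drop = FALSE]

    combos <- expand.grid(sender = typeLevels, receiver = typeLevels,
                          stringsAsFactors = FALSE)
    grid <- merge(combos, pairs, by = NULL)

    obs <- (obsMeans[cbind(grid$ligand, grid$sender)] +
            obsMeans[cbind(grid$receptor, grid$receiver)]) / 2
    fracL <- detFrac[cbind(grid$ligand, grid$sender)]
    fracR <- detFrac[cbind(grid$receptor, grid$receiver)]
    tested <- fracL >= fracMin & fracR >= fracMin

    exceed <- integer(nrow(grid))
    .withSeed(seed, {
        for (i in seq_len(nPerm)) {
            perm <- sample(types)
            pm <- .typeMeans(M, perm)[, typeLevels, drop = FALSE]
            nullScore <- (pm[cbind(grid$ligand, grid$sender)] +
                          pm[cbind(grid$receptor, grid$receiver)]) / 2
            exceed <- exceed + (nullScore >= obs)
        }
    })
    p <- (1 + exceed) / (nPerm + 1)
    reason <- ifelse(tested, NA_character_,
                     sprintf("expression fraction below %.2f", fracMin))
    data.frame(sender = grid$sender, receiver = grid$receiver,
               ligand = grid$ligand, receptor = grid$receptor,
               mean_score = ifelse(tested, obs, NA_real_),
               p = ifelse(tested, p, NA_real_),
               tested = tested, reason = reason, row.names = NULL)
}
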