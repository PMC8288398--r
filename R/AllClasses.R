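#' @import methods
#' @importFrom stats median p.adjust pnorm pt phyper t.test prcomp quantile
#'   rnbinom rnorm runif sd cor setNames aggregate
#' @importFrom utils read.delim write.table packageVersion head
NULL

#' Simulation configuration for synthetic islet scRNA-seq data
#'
#' Parameters of the negative-binomial (gamma-Poisson) count simulator used to
#' generate islet-like UMI datasets with planted ground truth. The default
#' configuration emulates a cross-sectional primate islet aging study: 16
#' donors (8 young, 8 old, both sexes in each group), 5575 cells across the
#' four endocrine types (alpha, beta, delta, PP), donor-level multiplicative
#' batch effects, an aging expression program concentrated in beta cells, and
#' age-inflated overdispersion restricted to alpha and beta cells.
#'
#' @slot nDonorsYoung,nDonorsOld number of donors per age group.
#' @slot nCellsTotal total number of cells to simulate.
#' @slot typeProportions named numeric, fraction of cells per cell type;
#'   must sum to 1.
#' @slot nGenes number of genes in the simulated universe.
#' @slot baselineMean per-gene baseline expected count (length \code{nGenes}).
#' @slot dispersion per-gene negative binomial dispersion (phi; variance is
#'   \code{mu + phi * mu^2}).
#' @slot donorEffectSd standard deviation (log2 scale) of the per-donor
#'   per-gene multiplicative batch effect.
#' @slot markerSpec data.frame with columns \code{gene}, \code{cell_type},
#'   \code{log2_enrichment}; marker genes multiplied by
#'   \code{2^log2_enrichment} in their own type.
#' @slot agingProgram data.frame with columns \code{gene}, \code{cell_type},
#'   \code{log2fc}; applied multiplicatively to cells of old donors of that
#'   type.
#' @slot noiseInflation named numeric per cell type; dispersion multiplier
#'   (>= 1) applied to old cells of that type.
#' @slot lrPairs data.frame with columns \code{ligand}, \code{receptor},
#'   \code{sender}, \code{receiver}, \code{planted}; planted pairs have their
#'   ligand enriched in the sender type and receptor in the receiver type.
#' @slot hubRegulator list with elements \code{gene}, \code{targets}
#'   (character) and \code{strength}; a per-cell latent activity multiplies
#'   the hub gene and its targets by \code{exp(strength * z)}.
#' @slot librarySizeMean,librarySizeSd mean and sd of the log-normal per-cell
#'   library-size factor.
#' @slot seed default random seed used when none is passed to
#'   \code{\link{simulateIslets}}.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateIslets}}
#' @export
setClass("SimConfig", representation(
    nDonorsYoung = "integer",
    nDonorsOld = "integer",
    nCellsTotal = "integer",
    typeProportions = "numeric",
    nGenes = "integer",
    baselineMean = "numeric",
    dispersion = "numeric",
    donorEffectSd = "numeric",
    markerSpec = "data.frame",
    agingProgram = "data.frame",
    noiseInflation = "numeric",
    lrPairs = "data.frame",
    hubRegulator = "list",
    librarySizeMean = "numeric",
    librarySizeSd = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (abs(sum(object@typeProportions) - 1) > 1e-9)
        msg <- c(msg, "typeProportions must sum to 1")
    if (is.null(names(object@typeProportions)) ||
        anyDuplicated(names(object@typeProportions)))
        msg <- c(msg, "typeProportions must have unique names")
    if (object@nDonorsYoung + object@nDonorsOld < 2L)
        msg <- c(msg, "need at least 2 donors in total")
    if (length(object@baselineMean) != object@nGenes)
        msg <- c(msg, "baselineMean must have length nGenes")
    if (length(object@dispersion) != object@nGenes)
        msg <- c(msg, "dispersion must have length nGenes")
    if (any(object@baselineMean <= 0) || any(object@dispersion <= 0))
        msg <- c(msg, "baselineMean and dispersion must be positive")
    if (any(object@noiseInflation < 1))
        msg <- c(msg, "noiseInflation multipliers must be >= 1")
    if (!all(names(object@noiseInflation) %in% names(object@typeProportions)))
        msg <- c(msg, "noiseInflation names must be cell types")
    if (object@donorEffectSd < 0)
        msg <- c(msg, "donorEffectSd must be non-negative")
    if (object@librarySizeMean <= 0 || object@librarySizeSd < 0)
        msg <- c(msg, "library size parameters must be positive")
    # planted structure must live inside the gene universe
    universe <- geneUniverse(object)
    planted <- unique(c(object@markerSpec$gene, object@agingProgram$gene,
                        object@lrPairs$ligand, object@lrPairs$receptor,
                        object@hubRegulator$gene, object@hubRegulator$targets))
    if (!all(planted %in% universe))
        msg <- c(msg, "all planted genes must exist in the gene universe")
    badType <- setdiff(c(object@markerSpec$cell_type,
                         object@agingProgram$cell_type,
                         object@lrPairs$sender, object@lrPairs$receiver),
                       names(object@typeProportions))
    if (length(badType))
        msg <- c(msg, paste("unknown cell type(s):",
                            paste(unique(badType), collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' Records everything the simulator planted, so recovery by the analysis
#' stages can be scored: per-cell assignments, aging differential expression
#' programs, noise-inflated types, planted ligand-receptor pairs, and the hub
#' regulator with its targets.
#'
#' @slot cellInfo data.frame with one row per simulated cell (cell_id,
#'   donor_id, age_group, sex, cell_type).
#' @slot agingDEGs data.frame (gene, cell_type, log2fc) of planted aging
#'   program genes.
#' @slot markerSpec planted marker table, as in \code{\linkS4class{SimConfig}}.
#' @slot noiseInflation named numeric of dispersion multipliers per type.
#' @slot lrPairs planted ligand-receptor table.
#' @slot hubRegulator list(gene, targets, strength).
#' @slot typeMeans matrix of expected per-gene means per (type, age) group.
#'
#' @seealso \code{\link{truthReport}}
#' @export
setClass("SimTruth", representation(
    cellInfo = "data.frame",
    agingDEGs = "data.frame",
    markerSpec = "data.frame",
    noiseInflation = "numeric",
    lrPairs = "data.frame",
    hubRegulator = "list",
    typeMeans = "matrix"
))

setValidity("SimTruth", function(object) {
    msg <- character()
    if (anyDuplicated(object@cellInfo$cell_id))
        msg <- c(msg, "cell ids must be unique")
    universe <- rownames(object@typeMeans)
    if (!all(object@agingDEGs$gene %in% universe))
        msg <- c(msg, "aging DEG genes must be a subset of the gene universe")
    if (length(msg)) msg else TRUE
})

#' An age-separating principal component
#'
#' Result of scanning principal components of one cell type for an axis that
#' separates young from old cells consistently across every donor. Scores are
#' oriented so that old cells lie on the positive side.
#'
#' @slot cellType the cell type analysed.
#' @slot pcIndex 1-based index of the selected component.
#' @slot orientation +1 or -1; the sign applied to the raw scores.
#' @slot scores named numeric of oriented per-cell scores.
#' @slot auc cell-level area under the ROC curve for old versus young along
#'   the oriented axis (in [0.5, 1]).
#' @slot donorMedians data.frame (donor_id, age_group, median_score,
#'   consistent) of per-donor median scores and the consistency flag.
#' @slot loading named numeric gene loading of the selected component (after
#'   orientation).
#' @slot midpoint the midpoint between the group median scores, used for
#'   young-like/old-like assignment.
#'
#' @seealso \code{\link{selectAgePC}}, \code{\link{assignAgeStates}}
#' @export
setClass("AgingAxis", representation(
    cellType = "character",
    pcIndex = "integer",
    orientation = "numeric",
    scores = "numeric",
    auc = "numeric",
    donorMedians = "data.frame",
    loading = "numeric",
    midpoint = "numeric"
))

setValidity("AgingAxis", function(object) {
    msg <- character()
    if (object@auc < 0.5 - 1e-12 || object@auc > 1 + 1e-12)
        msg <- c(msg, "auc must lie in [0.5, 1] after orientation")
    if (!object@orientation %in% c(-1, 1))
        msg <- c(msg, "orientation must be +1 or -1")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class gene identifiers of the simulated universe.
#' @param object,config a \code{SimConfig}.
#' @export
geneUniverse <- function(config) {
    attr(config@baselineMean, "gene_ids")
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes x", object@nCellsTotal, "cells\n")
    cat("  donors:", object@nDonorsYoung, "young +", object@nDonorsOld,
        "old; donor effect sd =", object@donorEffectSd, "\n")
    cat("  types:", paste(sprintf("%s %.2f", names(object@typeProportions),
                                  object@typeProportions), collapse = ", "), "\n")
    infl <- object@noiseInflation[object@noiseInflation > 1]
    cat("  noise inflation:",
        if (length(infl)) paste(sprintf("%s x%.2f", names(infl), infl),
                                collapse = ", ") else "none", "\n")
    cat("  aging program:", nrow(object@agingProgram), "gene-type entries;",
        "hub", object@hubRegulator$gene, "->",
        length(object@hubRegulator$targets), "targets\n")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth:", nrow(object@cellInfo), "cells,",
        nrow(object@typeMeans), "genes\n")
    cat("  planted aging DEGs:", nrow(object@agingDEGs), "\n")
    cat("  planted LR pairs:", sum(object@lrPairs$planted), "of",
        nrow(object@lrPairs), "\n")
    cat("  hub:", object@hubRegulator$gene, "->",
        length(object@hubRegulator$targets), "targets\n")
})

setMethod("show", "AgingAxis", function(object) {
    cat("AgingAxis for", object@cellType, "cells: PC", object@pcIndex,
        sprintf("(orientation %+d)\n", as.integer(object@orientation)))
    cat("  old-vs-young AUC:", round(object@auc, 4), "\n")
    cat("  donor consistency:", sum(object@donorMedians$consistent), "of",
        nrow(object@donorMedians), "donors\n")
})

#' @describeIn AgingAxis-class oriented per-cell scores.
#' @param axis an \code{AgingAxis}.
#' @export
axisScores <- function(axis) axis@scores

#' @describeIn AgingAxis-class index of the selected principal component.
#' @export
axisPC <- function(axis) axis@pcIndex

#' @describeIn AgingAxis-class old-versus-young AUC along the oriented axis.
#' @export
axisAUC <- function(axis) axis@auc

#' @describeIn AgingAxis-class oriented gene loading of the selected
#'   component.
#' @export
axisLoading <- function(axis) axis@loading

#' @describeIn SimTruth-class per-cell truth table.
#' @param truth a \code{SimTruth}.
#' @export
truthCells <- function(truth) truth@cellInfo

#' @describeIn SimTruth-class planted aging DEG table.
#' @export
truthAgingDEGs <- function(truth) truth@agingDEGs
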