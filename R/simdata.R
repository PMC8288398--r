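# Synthetic islet scRNA-seq generator: negative-binomial counts over a
# gene x (type, age, donor) mean hierarchy with planted aging structure.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
    }
    set.seed(seed)
    expr
}

#' Build a simulation configuration
#'
#' Constructs a \code{\linkS4class{SimConfig}}. With no arguments, returns the
#' default configuration emulating a primate islet aging study: 8 young + 8
#' old donors (4 female, 4 male per group), 5575 cells over four endocrine
#' types (alpha 0.50, beta 0.20, delta 0.15, PP 0.15), 5000 genes, log-normal
#' donor batch effects (sd 0.2), a beta-cell aging program of 100 genes at
#' |log2FC| = 1 plus a smaller alpha program (40 genes at |log2FC| = 0.8),
#' dispersion inflated 1.5-fold in old alpha and beta cells only, one planted
#' ligand-receptor pair (TTR in alpha senders, DDR1 on beta receivers) among
#' background pairs, and an HSPA5-like hub regulator driving 30 targets
#' through a per-cell latent activity.
#'
#' Baseline expression and dispersion are drawn once, deterministically from
#' \code{seed}, from log-normal and gamma laws chosen so that a typical cell
#' detects roughly 4400 genes; hormone markers (GCG, INS, SST, PPY) are given
#' high baselines and strong within-type enrichment as in real islets.
#'
#' @param nDonorsYoung,nDonorsOld donors per age group (default 8 + 8).
#' @param nCellsTotal total cells (default 5575).
#' @param typeProportions named fractions per cell type, summing to 1.
#' @param nGenes size of the gene universe (default 5000).
#' @param baselineMean,dispersion optional per-gene vectors; drawn from
#'   \code{seed} when \code{NULL}.
#' @param donorEffectSd sd (log2 scale) of the per-donor per-gene batch factor
#'   (default 0.2).
#' @param markerSpec,agingProgram,noiseInflation,lrPairs,hubRegulator planted
#'   structure; see \code{\linkS4class{SimConfig}}. Defaults as described
#'   above; pass \code{markerSpec = data.frame()} etc. to remove structure.
#' @param librarySizeMean,librarySizeSd log-normal per-cell library factor
#'   (default mean 1, sd 0.35).
#' @param seed integer; seeds both the deterministic draw of baseline
#'   parameters and, by default, \code{\link{simulateIslets}}.
#' @return a validated \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nCellsTotal = 200L, nGenes = 300L, seed = 1L)
#' cfg
#' @export
simConfig <- function(nDonorsYoung = 8L, nDonorsOld = 8L,
                      nCellsTotal = 5575L,
                      typeProportions = c(alpha = 0.50, beta = 0.20,
                                          delta = 0.15, PP = 0.15),
                      nGenes = 5000L,
                      baselineMean = NULL, dispersion = NULL,
                      donorEffectSd = 0.2,
                      markerSpec = NULL, agingProgram = NULL,
                      noiseInflation = NULL, lrPairs = NULL,
                      hubRegulator = NULL,
                      librarySizeMean = 1, librarySizeSd = 0.35,
                      seed = 1L) {
    nGenes <- as.integer(nGenes)
    genes <- sprintf("g%05d", seq_len(nGenes))

    drawn <- .withSeed(as.integer(seed) + 7L, {
        list(base = stats::rlnorm(nGenes, meanlog = log(4), sdlog = 0.8),
             phi = stats::rgamma(nGenes, shape = 4, rate = 4 / 0.3))
    })
    if (is.null(baselineMean)) baselineMean <- drawn$base
    if (is.null(dispersion)) dispersion <- pmax(drawn$phi, 0.05)

    types <- names(typeProportions)
    hasIsletTypes <- all(c("alpha", "beta", "delta", "PP") %in% types)

    # Canonical gene symbols are assigned to fixed slots of the universe so
    # planted structure is stable across configurations of the same size.
    if (hasIsletTypes && nGenes >= 400L) {
        symbols <- c(GCG = 1L, INS = 2L, SST = 3L, PPY = 4L, IAPP = 5L,
                     TTR = 6L, DDR1 = 7L, HSPA5 = 8L, HSP90B1 = 9L)
        genes[symbols] <- names(symbols)
        baselineMean[symbols[c("GCG", "INS", "SST", "PPY")]] <- 40
        baselineMean[symbols["IAPP"]] <- 20
        baselineMean[c(symbols[c("TTR", "DDR1", "HSPA5", "HSP90B1")])] <-
            c(15, 6, 12, 10)

        extra <- function(k, from) genes[seq(from, length.out = k)]
        if (is.null(markerSpec)) {
            mk <- rbind(
                data.frame(gene = c("GCG", "INS", "SST", "PPY"),
                           cell_type = c("alpha", "beta", "delta", "PP"),
                           log2_enrichment = 4),
                data.frame(gene = "IAPP", cell_type = "beta",
                           log2_enrichment = 3),
                data.frame(gene = "TTR", cell_type = "alpha",
                           log2_enrichment = 3),
                data.frame(gene = "DDR1", cell_type = "beta",
                           log2_enrichment = 2),
                data.frame(gene = rep(extra(48L, 10L), times = 1),
                           cell_type = rep(c("alpha", "beta", "delta", "PP"),
                                           each = 12),
                           log2_enrichment = 2.2))
            markerSpec <- mk
            # keep auxiliary markers comfortably detectable
            baselineMean[match(extra(48L, 10L), genes)] <-
                pmax(baselineMean[match(extra(48L, 10L), genes)], 3)
        }
        if (is.null(agingProgram)) {
            betaGenes <- c("HSP90B1", "HSPA5", extra(98L, 60L))
            alphaGenes <- extra(40L, 160L)
            agingProgram <- rbind(
                data.frame(gene = betaGenes, cell_type = "beta",
                           log2fc = c(rep(1, 80), rep(-1, 20))),
                data.frame(gene = alphaGenes, cell_type = "alpha",
                           log2fc = c(rep(0.8, 30), rep(-0.8, 10))))
            idx <- match(c(betaGenes, alphaGenes), genes)
            baselineMean[idx] <- pmax(baselineMean[idx], 3)
        }
        if (is.null(hubRegulator)) {
            hubRegulator <- list(gene = "HSPA5",
                                 targets = extra(30L, 62L),
                                 strength = 0.35)
        }
        if (is.null(lrPairs)) {
            bgL <- extra(31L, 210L)
            bgR <- extra(31L, 250L)
            idx <- match(c(bgL, bgR), genes)
            baselineMean[idx] <- pmax(baselineMean[idx], 3)
            combos <- expand.grid(sender = types, receiver = types,
                                  stringsAsFactors = FALSE)
            k <- rep(seq_along(bgL), length.out = 62)
            cmb <- combos[rep(seq_len(nrow(combos)), length.out = 62), ]
            lrPairs <- rbind(
                data.frame(ligand = "TTR", receptor = "DDR1",
                           sender = "alpha", receiver = "beta",
                           planted = TRUE),
                data.frame(ligand = bgL[k], receptor = bgR[k],
                           sender = cmb$sender, receiver = cmb$receiver,
                           planted = FALSE))
            rownames(lrPairs) <- NULL
        }
        if (is.null(noiseInflation))
            noiseInflation <- c(alpha = 1.5, beta = 1.5, delta = 1, PP = 1)
    }
    if (is.null(markerSpec))
        markerSpec <- data.frame(gene = character(), cell_type = character(),
                                 log2_enrichment = numeric())
    if (is.null(agingProgram))
        agingProgram <- data.frame(gene = character(), cell_type = character(),
                                   log2fc = numeric())
    if (is.null(noiseInflation))
        noiseInflation <- setNames(rep(1, length(types)), types)
    if (is.null(lrPairs))
        lrPairs <- data.frame(ligand = character(), receptor = character(),
                              sender = character(), receiver = character(),
                              planted = logical())
    if (is.null(hubRegulator))
        hubRegulator <- list(gene = character(), targets = character(),
                             strength = 0)

    attr(baselineMean, "gene_ids") <- genes
    new("SimConfig",
        nDonorsYoung = as.integer(nDonorsYoung),
        nDonorsOld = as.integer(nDonorsOld),
        nCellsTotal = as.integer(nCellsTotal),
        typeProportions = typeProportions,
        nGenes = nGenes,
        baselineMean = baselineMean,
        dispersion = dispersion,
        donorEffectSd = donorEffectSd,
        markerSpec = markerSpec,
        agingProgram = agingProgram,
        noiseInflation = noiseInflation,
        lrPairs = lrPairs,
        hubRegulator = hubRegulator,
        librarySizeMean = librarySizeMean,
        librarySizeSd = librarySizeSd,
        seed = as.integer(seed))
}

#' Simulate an islet scRNA-seq dataset with known ground truth
#'
#' Draws UMI counts from a negative-binomial (gamma-Poisson) hierarchy: the
#' expected count of gene g in cell c is the product of the gene baseline, a
#' cell-type marker enrichment, an aging-program fold change (old donors
#' only), a per-donor per-gene log-normal batch factor, a hub-regulator latent
#' activity (hub gene and targets only), and a per-cell log-normal library
#' factor. Dispersion is the per-gene value times the configured inflation
#' multiplier for old cells of flagged types. The draw is deterministic given
#' \code{seed} and leaves the caller's RNG state untouched.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param seed integer seed; defaults to the seed recorded in the config.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay
#'   (genes x cells, integer), per-cell metadata columns (\code{cell_id},
#'   \code{donor_id}, \code{age_group}, \code{sex}, \code{cell_type}) in
#'   \code{colData}, and the \code{\linkS4class{SimTruth}} in
#'   \code{metadata(.)$sim_truth} (see \code{\link{simTruth}}).
#' @examples
#' sce <- simulateIslets(simConfig(nCellsTotal = 300L, nGenes = 400L), seed = 1)
#' table(sce$cell_type, sce$age_group)
#' @export
simulateIslets <- function(config, seed = config@seed) {
    validObject(config)
    .withSeed(as.integer(seed), .simulateIslets(config))
}

.simulateIslets <- function(config) {
    genes <- geneUniverse(config)
    G <- config@nGenes
    N <- config@nCellsTotal
    types <- names(config@typeProportions)
    K <- length(types)

    donors <- data.frame(
        donor_id = c(sprintf("Y%02d", seq_len(config@nDonorsYoung)),
                     sprintf("O%02d", seq_len(config@nDonorsOld))),
        age_group = rep(c("young", "old"),
                        c(config@nDonorsYoung, config@nDonorsOld)))
    donors$sex <- unlist(lapply(c(config@nDonorsYoung, config@nDonorsOld),
                                function(n) rep_len(c("F", "M"), n)))

    # exact type counts: floor + largest remainders
    raw <- config@typeProportions * N
    nk <- floor(raw)
    rem <- N - sum(nk)
    if (rem > 0) {
        ord <- order(raw - nk, decreasing = TRUE)
        nk[ord[seq_len(rem)]] <- nk[ord[seq_len(rem)]] + 1
    }
    if (any(nk < 1)) stop("every cell type needs at least one cell")
    cellType <- sample(rep(types, nk))
    donorIdx <- sample.int(nrow(donors), N, replace = TRUE)
    cellDonor <- donors$donor_id[donorIdx]
    cellAge <- donors$age_group[donorIdx]
    cellSex <- donors$sex[donorIdx]
    cellIds <- sprintf("cell%05d", seq_len(N))

    # gene x type multipliers
    typeMult <- matrix(1, G, K, dimnames = list(genes, types))
    if (nrow(config@markerSpec))
        typeMult[cbind(match(config@markerSpec$gene, genes),
                       match(config@markerSpec$cell_type, types))] <-
            2^config@markerSpec$log2_enrichment
    agingMult <- matrix(1, G, K, dimnames = list(genes, types))
    if (nrow(config@agingProgram))
        agingMult[cbind(match(config@agingProgram$gene, genes),
                        match(config@agingProgram$cell_type, types))] <-
            2^config@agingProgram$log2fc

    typeIdx <- match(cellType, types)
    M <- config@baselineMean * typeMult[, typeIdx, drop = FALSE]
    oldCells <- which(cellAge == "old")
    if (length(oldCells))
        M[, oldCells] <- M[, oldCells] *
            agingMult[, typeIdx[oldCells], drop = FALSE]

    # donor batch effect in log2 units, consistent with every other
    # log-scale parameter of the configuration
    donorEff <- matrix(2^rnorm(G * nrow(donors), 0, config@donorEffectSd),
                       G, nrow(donors))
    M <- M * donorEff[, donorIdx, drop = FALSE]

    hub <- config@hubRegulator
    if (length(hub$gene) && length(hub$targets)) {
        z <- rnorm(N)
        hubRows <- match(unique(c(hub$gene, hub$targets)), genes)
        M[hubRows, ] <- M[hubRows, ] *
            rep(exp(hub$strength * z), each = length(hubRows))
    }

    sdlog <- sqrt(log(1 + (config@librarySizeSd / config@librarySizeMean)^2))
    libf <- stats::rlnorm(N, meanlog = log(config@librarySizeMean) -
                             sdlog^2 / 2, sdlog = sdlog)
    M <- M * rep(libf, each = G)

    # dispersion inflation for old cells of flagged types
    inflC <- rep(1, N)
    flag <- config@noiseInflation[cellType]
    inflC[cellAge == "old"] <- flag[cellAge == "old"]
    inflC[is.na(inflC)] <- 1
    counts <- matrix(0L, G, N, dimnames = list(genes, cellIds))
    for (v in sort(unique(inflC))) {
        cols <- which(inflC == v)
        cnt <- rnbinom(G * length(cols),
                       size = 1 / (config@dispersion * v),
                       mu = as.vector(M[, cols, drop = FALSE]))
        counts[, cols] <- as.integer(cnt)
    }

    cellInfo <- data.frame(cell_id = cellIds, donor_id = cellDonor,
                           age_group = cellAge, sex = cellSex,
                           cell_type = cellType)

    typeMeans <- cbind(config@baselineMean * typeMult,
                       config@baselineMean * typeMult * agingMult)
    colnames(typeMeans) <- c(paste0(types, ".young"), paste0(types, ".old"))
    rownames(typeMeans) <- genes

    truth <- new("SimTruth", cellInfo = cellInfo,
                 agingDEGs = config@agingProgram,
                 markerSpec = config@markerSpec,
                 noiseInflation = config@noiseInflation,
                 lrPairs = config@lrPairs,
                 hubRegulator = config@hubRegulator,
                 typeMeans = typeMeans)

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(cellInfo, row.names = cellIds))
    S4Vectors::metadata(sce)$sim_truth <- truth
    sce
}

#' Extract the planted ground truth from a simulated dataset
#'
#' @param sce a \code{SingleCellExperiment} produced by
#'   \code{\link{simulateIslets}}.
#' @return the \code{\linkS4class{SimTruth}} stored in the object metadata.
#' @export
simTruth <- function(sce) {
    truth <- S4Vectors::metadata(sce)$sim_truth
    if (is.null(truth)) stop("no simulation truth attached to this object")
    truth
}

#' Flat tables of everything the simulator planted
#'
#' @param truth a \code{\linkS4class{SimTruth}}.
#' @return a named list of data.frames: \code{aging_degs} (gene, cell_type,
#'   log2fc), \code{noise_inflated} (cell_type, multiplier),
#'   \code{lr_pairs}, and \code{hub_edges} (regulator, target).
#' @examples
#' sce <- simulateIslets(simConfig(nCellsTotal = 300L, nGenes = 400L), seed = 1)
#' lapply(truthReport(simTruth(sce)), head)
#' @export
truthReport <- function(truth) {
    hub <- truth@hubRegulator
    list(
        aging_degs = truth@agingDEGs,
        noise_inflated = data.frame(
            cell_type = names(truth@noiseInflation),
            multiplier = unname(truth@noiseInflation)),
        lr_pairs = truth@lrPairs,
        hub_edges = if (length(hub$gene) && length(hub$targets))
            data.frame(regulator = hub$gene, target = hub$targets)
        else data.frame(regulator = character(), target = character()))
}
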