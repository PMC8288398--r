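# Reading/writing expression bundles, quality control and normalization.

#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment counts logcounts
#'   logcounts<-
NULL

.checkRaw <- function(sce) {
    if (!"counts" %in% assayNames(sce))
        stop("expected a raw 'counts' assay")
    invisible(TRUE)
}

#' Read an expression matrix bundle
#'
#' Reads a genes x cells count matrix either from a MatrixMarket triplet
#' (\code{matrix.mtx} + \code{genes.tsv} + \code{barcodes.tsv}) or from a
#' dense TSV with gene ids in the first column, together with a cell metadata
#' TSV (columns \code{cell_id}, \code{donor_id}, \code{age_group}, \code{sex}
#' and optionally \code{cell_type}). Metadata rows are aligned to matrix
#' columns by \code{cell_id}, preserving matrix order.
#'
#' @param dir directory containing the bundle written by
#'   \code{\link{writeMatrixBundle}}; alternatively give the file paths.
#' @param matrix,genes,barcodes,metadata explicit paths overriding \code{dir}.
#' @return a \code{SingleCellExperiment} with a \code{counts} assay and the
#'   metadata in \code{colData}.
#' @export
readMatrixBundle <- function(dir = NULL, matrix = NULL, genes = NULL,
                             barcodes = NULL, metadata = NULL) {
    if (!is.null(dir)) {
        pick <- function(p, f) if (is.null(p)) file.path(dir, f) else p
        matrix <- pick(matrix, "matrix.mtx")
        genes <- pick(genes, "genes.tsv")
        barcodes <- pick(barcodes, "barcodes.tsv")
        metadata <- pick(metadata, "metadata.tsv")
    }
    for (f in c(matrix, metadata))
        if (!file.exists(f)) stop("file not found: ", f)

    if (grepl("\\.mtx$", matrix)) {
        m <- as.matrix(Matrix::readMM(matrix))
        geneIds <- read.delim(genes, header = FALSE)[[1]]
        cellIds <- read.delim(barcodes, header = FALSE)[[1]]
        if (nrow(m) != length(geneIds) || ncol(m) != length(cellIds))
            stop("matrix dimensions do not match the id files")
        dimnames(m) <- list(geneIds, cellIds)
    } else {
        tab <- read.delim(matrix, check.names = FALSE)
        geneIds <- tab[[1]]
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- geneIds
    }
    if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
    if (anyDuplicated(colnames(m))) stop("duplicate cell ids")
    storage.mode(m) <- "integer"

    meta <- read.delim(metadata)
    need <- c("cell_id", "donor_id", "age_group", "sex")
    if (!all(need %in% names(meta)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(m), meta$cell_id)
    if (length(missing))
        stop("cells missing from metadata: ",
             paste(head(missing, 5), collapse = ", "))
    meta <- meta[match(colnames(m), meta$cell_id), , drop = FALSE]
    if (anyNA(meta$age_group) || anyNA(meta$sex))
        stop("age_group and sex must be non-missing")

    SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(meta, row.names = meta$cell_id))
}

#' Write an expression matrix bundle
#'
#' Writes the \code{counts} assay as MatrixMarket \code{matrix.mtx} with
#' \code{genes.tsv}/\code{barcodes.tsv} id files, the cell metadata as
#' \code{metadata.tsv}, and, when simulation truth is attached, the
#' \code{\link{truthReport}} tables as \code{truth_*.tsv}.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeMatrixBundle <- function(sce, dir) {
    .checkRaw(sce)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(counts(sce), sparse = TRUE)
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    writeLines(rownames(sce), file.path(dir, "genes.tsv"))
    writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
    .writeTSV(as.data.frame(colData(sce)), file.path(dir, "metadata.tsv"))
    truth <- S4Vectors::metadata(sce)$sim_truth
    if (!is.null(truth)) {
        rep <- truthReport(truth)
        for (nm in names(rep))
            .writeTSV(rep[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
    }
    invisible(dir)
}

.writeTSV <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Quality-control filtering of cells
#'
#' Removes cells detecting fewer than \code{minGenes} genes or carrying fewer
#' than \code{minCounts} total UMIs. Genes are never removed here. The
#' defaults are configurable analysis parameters, recorded in the report.
#'
#' @param sce a \code{SingleCellExperiment} with raw counts.
#' @param minGenes minimum number of genes detected (> 0 counts) per cell.
#' @param minCounts minimum total counts per cell.
#' @return a list with \code{sce} (filtered) and \code{report}, a data.frame
#'   with one row per input cell (\code{cell_id}, \code{genes_detected},
#'   \code{total_counts}, \code{kept}) carrying the thresholds as attributes.
#' @examples
#' sce <- simulateIslets(simConfig(nCellsTotal = 200L, nGenes = 300L), seed = 1)
#' qc <- qcFilter(sce, minGenes = 100, minCounts = 200)
#' table(qc$report$kept)
#' @export
qcFilter <- function(sce, minGenes = 1000, minCounts = 10000) {
    .checkRaw(sce)
    if (minGenes < 0 || minCounts < 0) stop("thresholds must be non-negative")
    m <- counts(sce)
    detected <- colSums(m > 0)
    total <- colSums(m)
    kept <- detected >= minGenes & total >= minCounts
    report <- data.frame(cell_id = colnames(sce),
                         genes_detected = as.integer(detected),
                         total_counts = as.numeric(total),
                         kept = unname(kept))
    attr(report, "min_genes") <- minGenes
    attr(report, "min_counts") <- minCounts
    list(sce = sce[, kept], report = report)
}

#' Per-cell scaling and log2 transformation
#'
#' Scales each cell to a fixed total (\code{scale}, default 1e5, a UMI
#' counts-per-100k convention) and applies \code{log2(x + 1)}. The result is
#' stored in the \code{logcounts} assay; all downstream log2 fold changes in
#' this package are differences of group means of these values.
#'
#' @param sce a \code{SingleCellExperiment} with raw counts; zero-count cells
#'   must have been removed (see \code{\link{qcFilter}}).
#' @param scale target per-cell total before the log transform.
#' @return the object with a \code{logcounts} assay added.
#' @export
normalizeLog <- function(sce, scale = 1e5) {
    .checkRaw(sce)
    total <- colSums(counts(sce))
    if (any(total == 0))
        stop("cells with zero total counts present; run qcFilter first")
    ln <- log2(counts(sce) * rep(scale / total, each = nrow(sce)) + 1)
    logcounts(sce) <- ln
    sce
}

.getLogcounts <- function(sce) {
    if (!"logcounts" %in% assayNames(sce))
        stop("no 'logcounts' assay; run normalizeLog first")
    logcounts(sce)
}

#' Fraction of cells expressing a gene
#'
#' @param sce a \code{SingleCellExperiment}.
#' @param gene gene id.
#' @param cells optional character vector of cell ids (or logical/integer
#'   index) restricting the computation; defaults to all cells.
#' @param assay assay to use (\code{counts} or \code{logcounts}).
#' @return the fraction of the selected cells with value > 0, in [0, 1].
#' @export
expressionFraction <- function(sce, gene, cells = colnames(sce),
                               assay = "counts") {
    if (!gene %in% rownames(sce)) stop("unknown gene: ", gene)
    v <- assay(sce, assay)[gene, cells]
    if (length(v) == 0) stop("empty cell subset")
    mean(v > 0)
}

#' Read a marker specification TSV
#'
#' Expects columns \code{gene} and \code{cell_type} (and optionally
#' \code{log2_enrichment}).
#' @param path TSV file.
#' @return a data.frame.
#' @export
readMarkerSpec <- function(path) {
    tab <- read.delim(path)
    if (!all(c("gene", "cell_type") %in% names(tab)))
        stop("marker spec needs 'gene' and 'cell_type' columns")
    tab
}

#' Read a ligand-receptor pair TSV
#'
#' Expects columns \code{ligand} and \code{receptor}; duplicate pairs are
#' dropped.
#' @param path TSV file.
#' @return a data.frame.
#' @export
readLRPairs <- function(path) {
    tab <- read.delim(path)
    if (!all(c("ligand", "receptor") %in% names(tab)))
        stop("pair table needs 'ligand' and 'receptor' columns")
    unique(tab[, c("ligand", "receptor")])
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (set name, description, then member genes per line).
#' @return a named list of character vectors.
#' @export
readGMT <- function(path) {
    lines <- strsplit(readLines(path), "\t")
    sets <- lapply(lines, function(x) unique(x[-c(1, 2)]))
    names(sets) <- vapply(lines, `[`, "", 1)
    sets
}
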