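# End-to-end orchestration: run all stages from a single configuration and
# emit TSV outputs plus a machine-readable run manifest.

.defaultPipelineConfig <- function() {
    list(
        seed = 1L,
        output_dir = "islet_run",
        simulate = TRUE,
        sim = list(),                  # overrides passed to simConfig()
        input_dir = NULL,              # matrix bundle when simulate = FALSE
        marker_spec = NULL,            # TSV path; default: canonical hormones
        gene_sets = NULL,              # GMT path (optional)
        lr_pairs = NULL,               # TSV path; default: simulated truth
        tf_list = NULL,                # TSV/line file of regulator candidates
        qc = list(min_genes = 1000, min_counts = 10000),
        normalize = list(scale = 1e5),
        cluster = list(n_pcs = 5L, k_max = 8L),
        markers = list(lfc_min = 0.5, fdr_max = 0.05, frac_min = 0.25),
        noise = list(frac_min = 0.1),
        aging = list(max_pc = 10L, lfc_min = 0.5, fdr_max = 0.05,
                     stratify_by_sex = FALSE),
        interactions = list(n_perm = 500L, frac_min = 0.1),
        grn = list(weight_quantile = 0.90))
}

.validatePipelineConfig <- function(config) {
    def <- .defaultPipelineConfig()
    for (nm in names(config)) {
        if (!nm %in% names(def)) stop("unknown config field: ", nm)
        if (is.list(def[[nm]]) && nm != "sim")
            def[[nm]][names(config[[nm]])] <- config[[nm]]
        else def[[nm]] <- config[[nm]]
    }
    config <- def
    if (!isTRUE(config$simulate) && is.null(config$input_dir))
        stop("either simulate = TRUE or input_dir must be given")
    for (f in c("input_dir", "marker_spec", "gene_sets", "lr_pairs",
                "tf_list")) {
        if (!is.null(config[[f]]) && !file.exists(config[[f]]))
            stop("configured path does not exist: ", f, " = ", config[[f]])
    }
    config
}

# deterministic fan-out of the run seed into per-stage seeds
.stageSeeds <- function(seed, stages) {
    s <- .withSeed(as.integer(seed), sample.int(.Machine$integer.max - 1L,
                                                length(stages)))
    setNames(s, stages)
}

#' Run the full islet aging analysis pipeline
#'
#' Executes simulate (or load) -> qc -> normalize -> cluster -> annotate ->
#' markers -> noise -> aging axis (per type, optionally per sex) ->
#' signatures -> interactions -> grn, writing each stage's tables as TSV
#' under \code{output_dir} plus a JSON run manifest (package version, seeds,
#' parameters, counts in/out per stage). A stage failure halts the run with
#' the stage name and cause; outputs of completed stages are retained. The
#' run seed fans out deterministically into per-stage seeds.
#'
#' @param config a named list (see the YAML layout in the package vignette)
#'   or the path to a YAML file. Unspecified fields take documented defaults.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config = list()) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    config <- .validatePipelineConfig(config)
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

    stages <- c("simulate", "qc", "normalize", "cluster", "annotate",
                "markers", "noise", "aging_axis", "signatures",
                "interactions", "grn")
    seeds <- .stageSeeds(config$seed, stages)
    manifest <- list(package = "isletAging",
                     version = as.character(packageVersion("isletAging")),
                     seed = config$seed, config = config,
                     timestamp = format(Sys.time(), tz = "UTC"),
                     stages = list())
    out <- function(name) file.path(config$output_dir, name)
    record <- function(name, nIn, nOut, files, extra = list()) {
        manifest$stages[[length(manifest$stages) + 1L]] <<- c(
            list(name = name, status = "completed", seed = seeds[[name]],
                 n_in = nIn, n_out = nOut, outputs = as.list(files)), extra)
    }
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            manifest$stages[[length(manifest$stages) + 1L]] <<-
                list(name = name, status = "failed",
                     error = conditionMessage(e))
            .writeManifest(manifest, out("manifest.json"))
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    # -- simulate / load -----------------------------------------------------
    sce <- runStage("simulate", {
        if (isTRUE(config$simulate)) {
            cfg <- do.call(simConfig, c(config$sim,
                                        list(seed = seeds[["simulate"]])))
            s <- simulateIslets(cfg)
            writeMatrixBundle(s, out("simulated"))
            record("simulate", 0L, ncol(s), "simulated/")
            s
        } else {
            s <- readMatrixBundle(config$input_dir)
            record("simulate", ncol(s), ncol(s), character(0),
                   list(note = "loaded from input_dir"))
            s
        }
    })
    truth <- S4Vectors::metadata(sce)$sim_truth

    sce <- runStage("qc", {
        qc <- qcFilter(sce, config$qc$min_genes, config$qc$min_counts)
        .writeTSV(qc$report, out("qc_report.tsv"))
        record("qc", nrow(qc$report), sum(qc$report$kept), "qc_report.tsv",
               config$qc)
        qc$sce
    })
    sce <- runStage("normalize", {
        res <- normalizeLog(sce, config$normalize$scale)
        record("normalize", ncol(res), ncol(res), character(0),
               config$normalize)
        res
    })

    clusters <- runStage("cluster", {
        cl <- clusterCells(sce, config$cluster$n_pcs,
                           config$cluster$k_max,
                           seed = seeds[["cluster"]])
        .writeTSV(cl, out("clusters.tsv"))
        record("cluster", ncol(sce), length(unique(cl$cluster)),
               "clusters.tsv", config$cluster)
        cl
    })

    annotation <- runStage("annotate", {
        spec <- if (!is.null(config$marker_spec))
            readMarkerSpec(config$marker_spec)
        else data.frame(gene = c("GCG", "INS", "SST", "PPY"),
                        cell_type = c("alpha", "beta", "delta", "PP"))
        ann <- annotateTypes(sce, clusters, spec)
        .writeTSV(ann, out("cell_types.tsv"))
        record("annotate", ncol(sce), sum(ann$cell_type != "unassigned"),
               "cell_types.tsv")
        ann
    })
    cellTypes <- annotation$cell_type[match(colnames(sce),
                                            annotation$cell_id)]
    analysedTypes <- setdiff(sort(unique(cellTypes)), "unassigned")

    runStage("markers", {
        mk <- findTypeMarkers(sce, setNames(cellTypes, colnames(sce)),
                              config$markers$lfc_min, config$markers$fdr_max,
                              config$markers$frac_min)
        .writeTSV(mk, out("markers.tsv"))
        record("markers", nrow(sce), nrow(mk), "markers.tsv", config$markers)
    })

    noiseTests <- runStage("noise", {
        rows <- list(); files <- character(0)
        for (tp in analysedTypes) {
            nv <- transcriptionalNoise(sce, tp, config$noise$frac_min,
                                       types = cellTypes)
            f <- paste0("noise_", tp, ".tsv")
            .writeTSV(nv, out(f))
            files <- c(files, f)
            ct <- compareNoise(nv)
            rows[[tp]] <- data.frame(cell_type = tp, t = ct$t, p = ct$p,
                                     mean_old = ct$mean_old,
                                     mean_young = ct$mean_young)
        }
        tab <- do.call(rbind, rows)
        .writeTSV(tab, out("noise_tests.tsv"))
        record("noise", ncol(sce), nrow(tab),
               c(files, "noise_tests.tsv"), config$noise)
        tab
    })

    agingRes <- runStage("aging_axis", {
        res <- list(); files <- character(0); axRows <- list()
        for (tp in analysedTypes) {
            r <- agingAxisDEGs(sce, tp, maxPC = config$aging$max_pc,
                               seed = seeds[["aging_axis"]],
                               lfcMin = config$aging$lfc_min,
                               fdrMax = config$aging$fdr_max,
                               types = cellTypes)
            dd <- directDEGs(sce, tp, config$aging$lfc_min,
                             config$aging$fdr_max, types = cellTypes)
            f <- paste0("degs_direct_", tp, ".tsv")
            .writeTSV(dd, out(f)); files <- c(files, f)
            if (!is.null(r$axis)) {
                f2 <- paste0("degs_axis_", tp, ".tsv")
                .writeTSV(r$degs, out(f2))
                f3 <- paste0("age_states_", tp, ".tsv")
                .writeTSV(r$assignment, out(f3))
                files <- c(files, f2, f3)
                axRows[[tp]] <- data.frame(
                    cell_type = tp, pc_index = axisPC(r$axis),
                    auc = axisAUC(r$axis), n_degs = nrow(r$degs))
            } else {
                axRows[[tp]] <- data.frame(cell_type = tp, pc_index = NA,
                                           auc = NA, n_degs = NA)
            }
            r$direct <- dd
            res[[tp]] <- r
            if (isTRUE(config$aging$stratify_by_sex)) {
                st <- tryCatch(
                    stratifiedDEGs(sce, tp, maxPC = config$aging$max_pc,
                                   seed = seeds[["aging_axis"]],
                                   lfcMin = config$aging$lfc_min,
                                   fdrMax = config$aging$fdr_max,
                                   types = cellTypes),
                    warning = function(w) NULL)
                if (!is.null(st)) res[[tp]]$stratified <- st
            }
        }
        axTab <- do.call(rbind, axRows)
        .writeTSV(axTab, out("aging_axes.tsv"))
        record("aging_axis", ncol(sce), sum(!is.na(axTab$pc_index)),
               c("aging_axes.tsv", files),
               config$aging)
        res
    })

    runStage("signatures", {
        geneLists <- if (!is.null(config$gene_sets))
            readGMT(config$gene_sets)
        else if (!is.null(truth) && nrow(truth@agingDEGs))
            split(truth@agingDEGs$gene, truth@agingDEGs$cell_type)
        else list(top_variable = rownames(sce)[
            order(-.colSds(t(.getLogcounts(sce))))[seq_len(50)]])
        fc <- foldchangeMatrix(sce, unique(unlist(geneLists)),
                               cellTypes = analysedTypes,
                               lfcMin = config$aging$lfc_min,
                               fdrMax = config$aging$fdr_max,
                               types = cellTypes)
        .writeTSV(data.frame(gene = rownames(fc), fc, check.names = FALSE),
                  out("foldchange_matrix.tsv"))
        # GSEA on the first type with an axis-based DEG ranking
        gres <- NULL
        for (tp in analysedTypes) {
            if (is.null(agingRes[[tp]]$axis)) next
            full <- callDEGs(sce,
                agingRes[[tp]]$assignment$cell_id[
                    agingRes[[tp]]$assignment$state == "old-like"],
                agingRes[[tp]]$assignment$cell_id[
                    agingRes[[tp]]$assignment$state == "young-like"],
                all = TRUE)
            stats <- setNames(full$log2fc, full$gene)
            gres <- gseaTest(stats, geneLists, nPerm = 500L,
                             seed = seeds[["signatures"]])
            gres$ranking_type <- tp
            break
        }
        if (!is.null(gres)) .writeTSV(gres, out("gsea.tsv"))
        record("signatures", length(geneLists), nrow(fc),
               c("foldchange_matrix.tsv",
                 if (!is.null(gres)) "gsea.tsv"))
    })

    runStage("interactions", {
        pairs <- if (!is.null(config$lr_pairs)) readLRPairs(config$lr_pairs)
        else if (!is.null(truth) && nrow(truth@lrPairs)) truth@lrPairs
        else stop("no ligand-receptor pairs available")
        res <- lrPermutationTest(sce, pairs, config$interactions$n_perm,
                                 config$interactions$frac_min,
                                 seed = seeds[["interactions"]],
                                 types = cellTypes)
        .writeTSV(res, out("interactions.tsv"))
        record("interactions", nrow(pairs), sum(res$tested),
               "interactions.tsv", config$interactions)
    })

    runStage("grn", {
        degGenes <- unique(unlist(lapply(agingRes, function(r)
            if (!is.null(r$degs)) r$degs$gene else r$direct$gene)))
        if (length(degGenes) < 5)
            degGenes <- rownames(sce)[order(-.colSds(
                t(.getLogcounts(sce))))[seq_len(100)]]
        regulators <- if (!is.null(config$tf_list))
            intersect(readLines(config$tf_list), degGenes)
        else degGenes
        edges <- inferNetwork(sce, regulators, degGenes,
                              weightQuantile = config$grn$weight_quantile)
        ranking <- hubRanking(edges)
        .writeTSV(edges, out("grn_edges.tsv"))
        .writeTSV(ranking, out("grn_hubs.tsv"))
        record("grn", length(degGenes), nrow(edges),
               c("grn_edges.tsv", "grn_hubs.tsv"), config$grn)
    })

    .writeManifest(manifest, out("manifest.json"))
    invisible(manifest)
}

.writeManifest <- function(manifest, path) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
}

#' Summarize a completed pipeline run
#'
#' Reads the manifest and stage outputs from a run directory and produces a
#' plain-text summary (\code{report.txt}) plus a per-type summary TSV:
#' cell counts and percentages per type and age group, the noise test table,
#' selected aging axes, DEG counts, top interactions and the hub ranking.
#' Missing stage outputs are listed; the report is still produced. Re-running
#' is idempotent.
#'
#' @param outputDir directory of a \code{\link{runPipeline}} run.
#' @return invisibly, the summary as a list.
#' @export
pipelineReport <- function(outputDir) {
    manifestPath <- file.path(outputDir, "manifest.json")
    if (!file.exists(manifestPath)) stop("no manifest in ", outputDir)
    manifest <- jsonlite::read_json(manifestPath)
    lines <- c("isletAging pipeline report",
               paste("run seed:", manifest$seed), "")
    summary <- list(manifest = manifest)
    missing <- character(0)
    readOut <- function(name) {
        p <- file.path(outputDir, name)
        if (!file.exists(p)) { missing <<- c(missing, name); return(NULL) }
        read.delim(p)
    }

    types <- readOut("cell_types.tsv")
    meta <- readOut(file.path("simulated", "metadata.tsv"))
    if (!is.null(types)) {
        if (!is.null(meta))
            types$age_group <- meta$age_group[match(types$cell_id,
                                                    meta$cell_id)]
        tab <- as.data.frame(table(cell_type = types$cell_type,
                                   age_group = types$age_group %||% "all"))
        tab$percent <- round(100 * tab$Freq / sum(tab$Freq), 2)
        summary$cell_composition <- tab
        .writeTSV(tab, file.path(outputDir, "report_composition.tsv"))
        lines <- c(lines, "Cell composition (count, percent):",
                   paste(sprintf("  %s/%s: %d (%.2f%%)", tab$cell_type,
                                 tab$age_group, tab$Freq, tab$percent)), "")
    }
    noise <- readOut("noise_tests.tsv")
    if (!is.null(noise)) {
        summary$noise_tests <- noise
        lines <- c(lines, "Transcriptional noise, old vs young (Welch t):",
                   paste(sprintf("  %s: t = %.2f, p = %.3g", noise$cell_type,
                                 noise$t, noise$p)), "")
    }
    axes <- readOut("aging_axes.tsv")
    if (!is.null(axes)) {
        summary$aging_axes <- axes
        lines <- c(lines, "Aging axes:",
                   paste(vapply(seq_len(nrow(axes)), function(i) {
                       if (is.na(axes$pc_index[i]))
                           sprintf("  %s: not discriminated",
                                   axes$cell_type[i])
                       else sprintf("  %s: PC%d, AUC %.3f, %d DEGs",
                                    axes$cell_type[i], axes$pc_index[i],
                                    axes$auc[i], axes$n_degs[i])
                   }, "")), "")
    }
    inter <- readOut("interactions.tsv")
    if (!is.null(inter)) {
        tested <- inter[inter$tested == TRUE, , drop = FALSE]
        top <- head(tested[order(tested$p, -tested$mean_score), ], 5)
        summary$top_interactions <- top
        lines <- c(lines, "Top ligand-receptor interactions:",
                   paste(sprintf("  %s->%s %s:%s score %.2f p %.3g",
                                 top$sender, top$receiver, top$ligand,
                                 top$receptor, top$mean_score, top$p)), "")
    }
    hubs <- readOut("grn_hubs.tsv")
    if (!is.null(hubs)) {
        summary$hubs <- head(hubs, 5)
        lines <- c(lines, "Top network hubs:",
                   paste(sprintf("  %s (degree %d)", head(hubs$regulator, 5),
                                 head(hubs$degree, 5))), "")
    }
    if (length(missing))
        lines <- c(lines, "Missing stage outputs:",
                   paste(" ", missing))
    writeLines(lines, file.path(outputDir, "report.txt"))
    summary$missing <- missing
    invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
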