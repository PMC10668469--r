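.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    invisible(path)
}

.deToTable <- function(de) {
    data.frame(feature_id = rownames(de), as.data.frame(de),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Run the full synthetic-study pipeline
#'
#' Executes simulate -> differential expression (small RNA and mRNA) ->
#' temporal clustering -> anti-correlation network -> protein concordance
#' -> reporter analysis, writing every stage's table plus a run log
#' (resolved configuration and seed) and a ground-truth recovery report.
#' Reruns with identical configuration and seed are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param simConfig a [simulationConfig()] describing the synthetic study.
#' @param outdir output directory (created if needed).
#' @param seed integer seed; defaults to `config$seed`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        simConfig = simulationConfig(),
                        outdir, seed = config$seed) {
    validatePipelineConfig(config)
    validateSimulationConfig(simConfig)
    if (missing(outdir)) stop("outdir is required")
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(seed)

    ## --- simulate ---------------------------------------------------------
    study <- simulateStudy(simConfig, seed = seed)
    writeCountMatrix(study$smallRna, file.path(outdir, "counts_smallrna.tsv"))
    writeCountMatrix(study$mrna, file.path(outdir, "counts_mrna.tsv"))
    .writeTsv(data.frame(as.data.frame(colData(study$smallRna)),
                         stringsAsFactors = FALSE),
              file.path(outdir, "samples_smallrna.tsv"))
    .writeTsv(data.frame(as.data.frame(colData(study$mrna)),
                         stringsAsFactors = FALSE),
              file.path(outdir, "samples_mrna.tsv"))
    writeTargetMap(study$targetMap, file.path(outdir, "target_map.tsv"))
    writeGmt(study$geneSets, file.path(outdir, "gene_sets.gmt"))
    .writeTsv(data.frame(protein_id = rownames(study$proteins$abundance),
                         study$proteins$abundance, check.names = FALSE),
              file.path(outdir, "proteins.tsv"))
    for (part in names(study$truth))
        .writeTsv(study$truth[[part]],
                  file.path(outdir, sprintf("truth_%s.tsv", part)))

    ## --- differential expression -----------------------------------------
    smallUniq <- suppressMessages(filterUniqueFeatures(study$smallRna))
    deSmall <- fitNbContinuous(smallUniq)
    .writeTsv(.deToTable(deSmall), file.path(outdir, "de_smallrna.tsv"))
    deMrna <- fitNbContinuous(study$mrna)
    .writeTsv(.deToTable(deMrna), file.path(outdir, "de_mrna.tsv"))
    mirFeatures <- rownames(smallUniq)[featureSubtype(smallUniq) == "miRNA"]
    deMir <- deSmall[intersect(rownames(deSmall), mirFeatures), ,
                     drop = FALSE]
    .writeTsv(.deToTable(deMir), file.path(outdir, "de_mirna.tsv"))

    ## --- temporal clustering ---------------------------------------------
    sfS <- metadata(deSmall)$sizeFactors
    normSmall <- normalizeCounts(smallUniq, sfS, log2 = TRUE)
    sigMir <- rownames(deMir)[!is.na(deMir$padj) &
                              deMir$padj < config$alphaDe]
    clusters <- NULL
    if (length(sigMir) >= config$minClusterSize) {
        clusters <- tryCatch({
            z <- binMeanZscores(normSmall[sigMir, , drop = FALSE],
                                gestationalAge(smallUniq), config$binEdges)
            .writeTsv(data.frame(feature_id = rownames(z), z,
                                 check.names = FALSE),
                      file.path(outdir, "zprofiles.tsv"))
            cl <- clusterZProfiles(z, minSize = config$minClusterSize,
                                   cutHeight = config$cutHeight)
            .writeTsv(data.frame(feature_id = names(cl$assignments),
                                 cluster = cl$assignments),
                      file.path(outdir, "clusters.tsv"))
            cl
        }, error = function(e) {
            message("clustering stage skipped: ", conditionMessage(e))
            NULL
        })
    }

    ## --- anti-correlation network ----------------------------------------
    sfM <- metadata(deMrna)$sizeFactors
    normMrna <- normalizeCounts(study$mrna, sfM, log2 = TRUE)
    sigMrna <- rownames(deMrna)[!is.na(deMrna$padj) &
                                deMrna$padj < config$alphaDe]
    pairs <- candidatePairs(sigMir, sigMrna, study$targetMap)
    edges <- correlatePairs(pairs, normSmall, normMrna, study$sharedSamples)
    .writeTsv(edges, file.path(outdir, "edges_all.tsv"))
    kept <- filterAnticorrelated(edges, pMax = config$alphaCorr,
                                 rMax = config$rMax)
    revalidateEdges(kept, pMax = config$alphaCorr, rMax = config$rMax)
    .writeTsv(kept, file.path(outdir, "edges_filtered.tsv"))
    groups <- suppressWarnings(partitionByMrnaDirection(kept, deMrna))
    .writeTsv(groups$up, file.path(outdir, "edges_mrna_up.tsv"))
    .writeTsv(groups$down, file.path(outdir, "edges_mrna_down.tsv"))
    topEdges <- selectTopFraction(groups$down, config$topFraction)
    .writeTsv(topEdges, file.path(outdir, "edges_top_fraction.tsv"))
    for (rc in config$figureRCuts)
        .writeTsv(thresholdEdges(kept, rc),
                  file.path(outdir, sprintf("edges_r_below_%s.tsv",
                                            gsub("-", "m", format(rc)))))
    if (nrow(kept)) {
        nodeIds <- c(unique(kept$mirna_id), unique(kept$mrna_id))
        nodes <- data.frame(
            nodeId = nodeIds,
            layer = rep(c("miRNA", "mRNA"),
                        c(length(unique(kept$mirna_id)),
                          length(unique(kept$mrna_id)))),
            stringsAsFactors = FALSE)
        writeNetwork(nodes,
                     data.frame(source = kept$mirna_id,
                                target = kept$mrna_id, r = kept$r,
                                p = kept$p, stringsAsFactors = FALSE),
                     file.path(outdir, "network.graphml"),
                     format = "graphml")
    }

    ## --- protein concordance / tripartite --------------------------------
    common <- commonProteinFilter(study$proteins$abundance)
    deProt <- fitTwoGroup(common, study$proteins$groups)
    .writeTsv(.deToTable(deProt), file.path(outdir, "de_protein.tsv"))
    conc <- concordantPairs(deProt, deMrna, alpha = config$alphaProtein)
    .writeTsv(conc, file.path(outdir, "concordant_proteins.tsv"))
    triUp <- buildTripartite(kept, deMir, deMrna, conc, "down-up-enriched")
    triDown <- buildTripartite(kept, deMir, deMrna, conc,
                               "up-down-depleted")
    writeNetwork(as.data.frame(networkNodes(triUp)),
                 as.data.frame(networkEdges(triUp)),
                 file.path(outdir, "tripartite_down_up_enriched.graphml"),
                 format = "graphml")
    writeNetwork(as.data.frame(networkNodes(triDown)),
                 as.data.frame(networkEdges(triDown)),
                 file.path(outdir, "tripartite_up_down_depleted.graphml"),
                 format = "graphml")

    ## --- reporter analysis ------------------------------------------------
    targetGenes <- intersect(unique(study$targetMap$mrna_id), sigMrna)
    repStats <- suppressWarnings(
        geneStats(deMrna[targetGenes, , drop = FALSE]))
    reporter <- runReporter(repStats, study$geneSets, minK = config$minK,
                            maxK = config$maxK, nPerm = config$nPerm,
                            alpha = config$alphaReporter)
    .writeTsv(reporter$records, file.path(outdir, "reporter_metabolites.tsv"))
    .writeTsv(reporter$skipped, file.path(outdir, "reporter_skipped.tsv"))
    nControl <- min(length(targetGenes), length(sigMrna))
    control <- randomControlRun(deMrna, n = nControl, gsc = study$geneSets,
                                alphaDe = config$alphaDe,
                                minK = config$minK, maxK = config$maxK,
                                nPerm = config$nPerm,
                                alpha = config$alphaReporter)
    .writeTsv(control$records, file.path(outdir, "reporter_control.tsv"))

    ## --- recovery report ---------------------------------------------------
    recovery <- scoreRecovery(study, deSmall, deMir, deMrna, kept, clusters,
                              deProt, conc, list(up = triUp, down = triDown),
                              reporter, alphaDe = config$alphaDe)
    .writeTsv(recovery, file.path(outdir, "recovery_report.tsv"))

    ## --- run log ------------------------------------------------------------
    log <- c(sprintf("tempomir %s", as.character(packageVersion("tempomir"))),
             sprintf("seed: %d", seed),
             "pipeline config:",
             paste0("  ", names(config), " = ",
                    vapply(config, function(v) paste(format(v), collapse = ","),
                           "")),
             "simulation config:",
             paste0("  ", names(simConfig), " = ",
                    vapply(simConfig, function(v)
                        paste(format(v), collapse = ","), "")))
    writeLines(log, file.path(outdir, "run_log.txt"))

    invisible(list(study = study, deSmall = deSmall, deMir = deMir,
                   deMrna = deMrna, clusters = clusters, edges = edges,
                   keptEdges = kept, topEdges = topEdges, deProt = deProt,
                   concordant = conc, tripartite = list(up = triUp,
                                                        down = triDown),
                   reporter = reporter, control = control,
                   recovery = recovery))
}

#' Score recovery of the planted ground truth
#'
#' Compares pipeline results with the synthetic study's ground truth:
#' edge precision/recall and decoy pass-rate, DE sensitivity, cluster ARI,
#' protein concordance recovery, tripartite path precision/recall and
#' reporter direction recovery.
#'
#' @param study a `SyntheticStudy`.
#' @param deSmall,deMir,deMrna,deProt [DEResults-class] tables.
#' @param keptEdges filtered anti-correlation edges.
#' @param clusters [clusterZProfiles()] output (or `NULL`).
#' @param concordant [concordantPairs()] output.
#' @param tripartite list of the two [TripartiteNetwork-class] objects.
#' @param reporter [runReporter()] output.
#' @param alphaDe DE cutoff used.
#' @return data.frame of named recovery metrics.
#' @export
scoreRecovery <- function(study, deSmall, deMir, deMrna, keptEdges, clusters,
                          deProt, concordant, tripartite, reporter,
                          alphaDe = 0.05) {
    truth <- study$truth
    metric <- function(name, value) data.frame(metric = name,
                                               value = value,
                                               stringsAsFactors = FALSE)
    out <- list()
    ## edges
    ek <- paste(keptEdges$mirna_id, keptEdges$mrna_id, sep = "\r")
    planted <- truth$edges[truth$edges$type == "planted", ]
    decoys <- truth$edges[truth$edges$type == "decoy", ]
    pk <- paste(planted$mirna_id, planted$mrna_id, sep = "\r")
    dk <- paste(decoys$mirna_id, decoys$mrna_id, sep = "\r")
    out$edge_recall <- metric("edge_recall", mean(pk %in% ek))
    out$edge_precision <- metric("edge_precision",
                                 if (length(ek)) mean(ek %in% pk) else NA)
    out$decoy_pass_rate <- metric("decoy_pass_rate", mean(dk %in% ek))
    ## DE recall on slope-DE mRNAs
    sigM <- rownames(deMrna)[!is.na(deMrna$padj) & deMrna$padj < alphaDe]
    deTrue <- truth$features$feature_id[truth$features$layer == "mRNA" &
                                        truth$features$is_de]
    out$mrna_de_recall <- metric("mrna_de_recall", mean(deTrue %in% sigM))
    ## clusters
    if (!is.null(clusters)) {
        lab <- setNames(truth$features$cluster_id, truth$features$feature_id)
        common <- intersect(names(clusters$assignments), names(lab)[!is.na(lab)])
        if (length(common) > 1L)
            out$cluster_ari <- metric("cluster_ari",
                adjustedRandIndex(clusters$assignments[common], lab[common]))
    }
    ## proteins: only proteins detected in every sample can be recovered
    ## (the common-protein filter is part of the method's input definition)
    detected <- rownames(commonProteinFilter(study$proteins$abundance))
    concTrue <- intersect(truth$proteins$protein_id[truth$proteins$concordant],
                          detected)
    out$protein_concordance_recall <- metric("protein_concordance_recall",
        if (length(concTrue)) mean(concTrue %in% concordant$protein_id)
        else NA)
    ## tripartite paths: planted edge whose target has a detectable
    ## true-concordant protein
    protGene <- intersect(truth$proteins$gene_id[truth$proteins$concordant],
                          detected)
    truePaths <- pk[planted$mrna_id %in% protGene]
    predPaths <- character()
    for (tri in tripartite) {
        e <- as.data.frame(networkEdges(tri))
        e <- e[e$type == "targeting", , drop = FALSE]
        predPaths <- c(predPaths,
                       paste(sub("^miRNA:", "", e$source),
                             sub("^mRNA:", "", e$target), sep = "\r"))
    }
    out$tripartite_recall <- metric("tripartite_recall",
        if (length(truePaths)) mean(truePaths %in% predPaths) else NA)
    out$tripartite_precision <- metric("tripartite_precision",
        if (length(predPaths)) mean(predPaths %in% truePaths) else NA)
    ## reporter
    rec <- reporter$records
    dirTruth <- setNames(truth$sets$direction, truth$sets$set_id)
    if (nrow(rec)) {
        evalDir <- dirTruth[rec$set_id]
        isDir <- evalDir %in% c("up", "down")
        out$reporter_direction_recall <- metric("reporter_direction_recall",
            if (any(isDir)) mean(rec$call[isDir] == evalDir[isDir]) else NA)
        out$reporter_null_call_rate <- metric("reporter_null_call_rate",
            if (any(!isDir)) mean(rec$call[!isDir] != "none") else NA)
    }
    do.call(rbind, out)
}
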