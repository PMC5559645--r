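#' @include synthetic.R dpcluster.R wgd.R signatures.R drivers.R
NULL

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Every
#' tunable is surfaced with the method's standard value as default:
#' presence-test error rate 1/200, at most 7 signatures per solution with
#' the 2\%/50-mutation exclusion and 0.02 Pearson improvement rule,
#' branches above 20 mutations for signature analysis, 100 bootstrap
#' resamples for WGD timing, targeted amplification at logR > 1, and
#' enrichment significance at q < 0.1.
#'
#' @param mutationFile,segmentFiles,purityFile Input paths; `segmentFiles`
#'   is a named vector (one per sample). Leave `NULL` with
#'   `simulate = TRUE` to generate a synthetic patient instead.
#' @param simulate Logical; simulate inputs with [simulatePatient()].
#' @param simulationArgs Arguments for [simulationConfig()].
#' @param outputDir Directory for stage outputs.
#' @param catalogFile Optional signature catalogue TSV; defaults to the
#'   synthetic catalogue.
#' @param tol Tree dominance tolerance (CCF), default 0.05.
#' @param errorRate Presence-test error rate, default 1/200.
#' @param iterations,burnIn Gibbs sweeps for clustering.
#' @param minClusterSize Small-cluster merge threshold (NULL = 1\% of
#'   mutations, floor 5).
#' @param maxSignatures,minShare,minCount,minImprovement,minBranchMutations
#'   Signature model-selection rules.
#' @param bootstrapB WGD bootstrap resamples, default 100.
#' @param qCutoff Enrichment significance threshold, default 0.1.
#' @param seed Integer seed for every stochastic stage.
#' @param stages Character subset of
#'   \code{c("cluster", "tree", "wgd", "signatures")}.
#' @return A validated config list.
#' @export
pipelineConfig <- function(mutationFile = NULL, segmentFiles = NULL,
                           purityFile = NULL, simulate = is.null(mutationFile),
                           simulationArgs = list(), outputDir = tempfile("run"),
                           catalogFile = NULL, tol = 0.05,
                           errorRate = 1 / 200, iterations = 1000,
                           burnIn = 500, minClusterSize = NULL,
                           maxSignatures = 7, minShare = 0.02,
                           minCount = 50, minImprovement = 0.02,
                           minBranchMutations = 20, bootstrapB = 100,
                           qCutoff = 0.1, seed = 1,
                           stages = c("cluster", "tree", "wgd",
                                      "signatures")) {
    if (!simulate) {
        if (is.null(mutationFile) || is.null(segmentFiles) ||
            is.null(purityFile))
            stopf("either simulate = TRUE or all of mutationFile, segmentFiles, purityFile")
    }
    stages <- match.arg(stages, several.ok = TRUE)
    as.list(environment())
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipelineConfig()] arguments.
#' @param ... Overrides applied after the file.
#' @return A validated config list.
#' @export
pipelineConfigFromYAML <- function(path, ...) {
    cfg <- yaml::read_yaml(path)
    over <- list(...)
    cfg[names(over)] <- over
    do.call(pipelineConfig, cfg)
}

#' Run the multi-sample evolution pipeline
#'
#' Executes the stages in order: load or simulate inputs, QC-filter
#' mutations against the segments, annotate copy number / multiplicity /
#' CCF, Dirichlet-process clustering, pigeonhole tree construction, WGD
#' timing (tetraploid genomes only), and per-branch signature refitting.
#' Writes `clusters.tsv`, `tree.nwk`, `branch_stats.tsv`,
#' `wgd_timing.json`, `signatures.tsv` and `run_log.txt` to the output
#' directory. Any stage failure halts with the stage name.
#'
#' @param config From [pipelineConfig()].
#' @return A list with elements `patient` (when simulated), `qc`,
#'   `clusters`, `tree`, `wgd`, `signatures`, `paths`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(config$outputDir, "run_log.txt")
    logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                                 file = logFile, append = TRUE)
    cat("", file = logFile)
    logLine("phyloCCF %s | seed %d",
            as.character(utils::packageVersion("phyloCCF")), config$seed)
    stage <- function(name, expr) {
        logLine("stage %s", name)
        tryCatch(expr, error = function(e)
            stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    }
    result <- list(paths = character(0))

    patient <- NULL
    if (isTRUE(config$simulate)) {
        patient <- stage("simulate", {
            args <- config$simulationArgs
            if (is.null(args$seed)) args$seed <- config$seed
            simulatePatient(do.call(simulationConfig, args))
        })
        ms <- mutations(patient)
        seg <- segments(patient)
        catalog <- if (is.null(config$catalogFile)) syntheticSignatureCatalog()
                   else readSignatureCatalog(config$catalogFile)
        result$patient <- patient
    } else {
        ms <- stage("load", {
            pur <- utils::read.delim(config$purityFile)
            purv <- stats::setNames(pur$purity, pur$sample)
            readMutationTable(config$mutationFile, purv)
        })
        seg <- stage("load-segments", {
            missing <- setdiff(colnames(ms), names(config$segmentFiles))
            if (length(missing))
                stopf("no segment file for sample %s", missing[1L])
            do.call(c, lapply(names(config$segmentFiles), function(s) {
                g <- readSegments(config$segmentFiles[[s]])
                g$sample <- s
                g
            }))
        })
        catalog <- if (is.null(config$catalogFile)) syntheticSignatureCatalog()
                   else readSignatureCatalog(config$catalogFile)
    }

    result$qc <- stage("qc", qcFilter(ms, seg))
    logLine("qc retained %.1f%% of %d mutations",
            100 * result$qc$retainedFraction, nrow(ms))
    kept <- stage("ccf", computeCCF(result$qc$retained, seg))

    if ("cluster" %in% config$stages) {
        result$clusters <- stage("cluster",
            dpCluster(kept, iterations = config$iterations,
                      burnIn = config$burnIn, seed = config$seed,
                      minClusterSize = config$minClusterSize))
        cpath <- file.path(config$outputDir, "clusters.tsv")
        cdf <- data.frame(cluster = seq_along(clusterSizes(result$clusters)),
                          size = clusterSizes(result$clusters),
                          round(ccf(result$clusters), 4))
        utils::write.table(cdf, cpath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        result$paths["clusters"] <- cpath
    }

    if ("tree" %in% config$stages && !is.null(result$clusters)) {
        rd <- SummarizedExperiment::rowData(kept)
        result$tree <- stage("tree",
            buildTree(result$clusters, tol = config$tol,
                      mutationClasses = stats::setNames(rd$class,
                                                        rownames(kept))))
        tpath <- file.path(config$outputDir, "tree.nwk")
        exportNewick(result$tree, file = tpath)
        bpath <- file.path(config$outputDir, "branch_stats.tsv")
        utils::write.table(branchStats(result$tree), bpath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        result$paths[c("tree", "branch_stats")] <- c(tpath, bpath)
    }

    if ("wgd" %in% config$stages && !is.null(result$tree)) {
        cn <- SummarizedExperiment::assay(kept, "totalCN")
        trunkIdx <- treeRootIndex(result$tree)
        trunkIds <- result$tree@branchMutations[[trunkIdx]]
        tetra <- rownames(kept)[rowSums(cn == 4) == ncol(kept)]
        use <- intersect(trunkIds, tetra)
        if (length(use) >= 20) {
            s1 <- colnames(kept)[1L]
            result$wgd <- stage("wgd",
                timeWGD(altCounts(kept)[use, s1], depths(kept)[use, s1],
                        purity(kept)[s1], B = config$bootstrapB,
                        seed = config$seed))
            wpath <- file.path(config$outputDir, "wgd_timing.json")
            jsonlite::write_json(list(t = result$wgd@t,
                                      ci = c(result$wgd@ciLow,
                                             result$wgd@ciHigh),
                                      pi = as.list(result$wgd@pi),
                                      n = result$wgd@nMutations),
                                 wpath, auto_unbox = TRUE, digits = NA)
            result$paths["wgd"] <- wpath
        } else logLine("wgd skipped: %d tetraploid trunk mutations",
                       length(use))
    }

    if ("signatures" %in% config$stages && !is.null(result$tree)) {
        result$signatures <- stage("signatures",
            branchSignatures(result$tree, kept, catalog,
                             minMutations = config$minBranchMutations,
                             maxSize = config$maxSignatures,
                             minShare = config$minShare,
                             minCount = config$minCount,
                             minImprovement = config$minImprovement))
        spath <- file.path(config$outputDir, "signatures.tsv")
        rows <- list()
        for (b in names(result$signatures)) {
            sol <- result$signatures[[b]]
            if (is.character(sol)) {
                rows[[b]] <- data.frame(branch = b, signature = NA,
                                        exposure = NA, r = NA, note = sol)
            } else {
                e <- exposures(sol)
                rows[[b]] <- data.frame(branch = b, signature = names(e),
                                        exposure = unname(e),
                                        r = reconstructionR(sol), note = "")
            }
        }
        utils::write.table(do.call(rbind, rows), spath, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        result$paths["signatures"] <- spath
    }
    logLine("done")
    result
}
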