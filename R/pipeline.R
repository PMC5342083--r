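#' @include AllClasses.R AllGenerics.R
NULL

#' Run the full age-trend analysis pipeline
#'
#' Executes the analysis stages in order: optional pre-processing,
#' moving-window sample weighting (when enabled), per-probe weighted
#' quadratic fits with F-test, BH adjustment and fold change, the joint
#' FDR + fold-change filter, Euclidean trend clustering with redundant-
#' cluster merging and inclination labelling, and absolute-correlation
#' clustering for age-position detection. The run is a pure function of
#' (inputs, config): identical reruns are bit-identical.
#'
#' When `outDir` is given, every stage output is materialized: the results
#' TSV, the volcano TSV, the weights TSV, the cluster membership TSV, the
#' age-position report and a run summary, each stamped with the config
#' fingerprint and seed in a `#` header line.
#'
#' @param dataset an [AgeExpressionSet-class], or a path to an expression
#'   TSV (then `metadataPath` is required).
#' @param config an [AnalysisConfig-class].
#' @param metadataPath sample metadata TSV when `dataset` is a path.
#' @param preprocess named list of arguments for [preprocessDataset()], or
#'   `NULL` to skip pre-processing.
#' @param outDir optional output directory.
#' @return List with `fits`, `filtered` (filter output), `directions`,
#'   `weights`, `trendClusters`, `agePosition` and `summary`.
#' @export
runPipeline <- function(dataset, config = analysisConfig(),
                        metadataPath = NULL, preprocess = NULL,
                        outDir = NULL) {
    if (is.character(dataset)) {
        if (is.null(metadataPath))
            stop("metadataPath is required when dataset is a file path")
        dataset <- readExpressionMatrix(dataset, metadataPath)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if (!is.null(preprocess))
        dataset <- stage("preprocess",
                         do.call(preprocessDataset,
                                 c(list(dataset), preprocess)))
    weights <- NULL
    if (config@weightingEnabled)
        weights <- stage("weights",
                         cohortWeights(dataset, config@windowHalfwidth))
    fits <- stage("fit", fitProbes(dataset, weights, config))
    filtered <- stage("filter",
                      filterProbes(fits, config@fdrThreshold,
                                   config@absFcThreshold))
    directions <- tabulateDirections(filtered$fits)
    sig <- filtered$fits
    trendClusters <- NULL
    agePosition <- NULL
    if (nrow(fitTable(sig)) >= 2L) {
        std <- standardizeTrajectories(sig)
        keepVar <- apply(std, 1, stats::sd) > 0
        std <- std[keepVar, , drop = FALSE]
        if (nrow(std) >= 2L) {
            kTrend <- min(config@kmeansK, nrow(std))
            trendClusters <- stage("cluster", labelInclinations(
                mergeRedundantClusters(
                    kmeansTrends(std, k = kTrend, metric = "euclidean",
                                 seed = config@randomSeed,
                                 ageGrid = ageGrid(sig),
                                 restarts = config@kmeansRestarts),
                    config@mergeCorrThreshold)))
            agePosition <- stage("age-position",
                detectAgePosition(std, ageGrid = ageGrid(sig),
                                  k = min(config@kmeansK, nrow(std)),
                                  seed = config@randomSeed,
                                  restarts = config@kmeansRestarts))
        }
    }
    summary <- list(
        probesIn = nrow(dataset),
        samples = ncol(dataset),
        weighting = config@weightingEnabled,
        nFDR = filtered$summary$nFDR,
        nFDRFC = filtered$summary$nFDRFC,
        directions = directions,
        nClusters = if (is.null(trendClusters)) 0L
                    else length(clusterSizes(trendClusters)),
        clusterInclinations = if (is.null(trendClusters)) character(0)
                              else inclinations(trendClusters),
        agePosition = if (is.null(agePosition)) NA_real_
                      else positionAge(agePosition),
        agePositionDecade = if (is.null(agePosition)) NA_integer_
                            else positionDecade(agePosition))
    result <- list(fits = fits, filtered = filtered,
                   directions = directions, weights = weights,
                   trendClusters = trendClusters, agePosition = agePosition,
                   summary = summary, config = config)
    if (!is.null(outDir))
        .writePipelineOutputs(result, dataset, outDir, config)
    result
}

# Materialize every stage output under outDir, each stamped with the
# config fingerprint + seed so runs are reproducible from the files alone.
.writePipelineOutputs <- function(result, dataset, outDir, config) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfg <- .configString(config)
    stamp <- sprintf("config_hash=%s seed=%d", .fnv1a(cfg),
                     config@randomSeed)
    writeResultsTable(result$fits, result$trendClusters,
                      file.path(outDir, "results.tsv"),
                      header = c(stamp, cfg))
    vt <- volcanoTable(result$fits, config@fdrThreshold,
                       config@absFcThreshold)
    con <- file(file.path(outDir, "volcano.tsv"), "w")
    writeLines(paste0("# ", stamp), con)
    utils::write.table(vt, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    if (!is.null(result$weights))
        writeWeightsTable(result$weights, ages(dataset),
                          file.path(outDir, "weights.tsv"))
    ap <- result$agePosition
    apLines <- c(paste0("# ", stamp),
                 "age\tdecade\tmethod\tsupport_pos\tsupport_neg\tsecondary")
    if (!is.null(ap)) {
        apLines <- c(apLines, paste(
            .fmtNum(ap@age), ifelse(is.na(ap@decade), "NA", ap@decade),
            ap@method, ap@supportSizes[1], ap@supportSizes[2],
            paste(.fmtNum(ap@secondary), collapse = ","), sep = "\t"))
    }
    writeLines(apLines, file.path(outDir, "age_position.tsv"))
    s <- result$summary
    writeLines(c(paste0("# ", stamp),
                 paste0("probes_in\t", s$probesIn),
                 paste0("samples\t", s$samples),
                 paste0("n_fdr\t", s$nFDR),
                 paste0("n_fdr_fc\t", s$nFDRFC),
                 paste0("positive\t", s$directions$positive),
                 paste0("negative\t", s$directions$negative),
                 paste0("n_clusters\t", s$nClusters),
                 paste0("age_position\t", .fmtNum(s$agePosition)),
                 paste0("age_position_decade\t", s$agePositionDecade)),
             file.path(outDir, "summary.tsv"))
    invisible(NULL)
}
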