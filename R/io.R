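#' @include AllClasses.R AllGenerics.R
NULL

#' Create or validate an analysis configuration
#'
#' All pipeline thresholds in one validated object. Defaults follow the
#' published analysis conventions: FDR < 0.05, absolute fold change >= 1.2,
#' a +/- 5 year weighting window, 10 K-means clusters merged at centroid
#' correlation 0.9, and a 1-year age grid.
#'
#' @param fdrThreshold,absFcThreshold,windowHalfwidth,kmeansK,
#'   mergeCorrThreshold,ageGridStep,randomSeed,weightingEnabled,fcMode,
#'   kmeansRestarts see [AnalysisConfig-class].
#' @return An [AnalysisConfig-class] object.
#' @export
analysisConfig <- function(fdrThreshold = 0.05, absFcThreshold = 1.2,
                           windowHalfwidth = 5, kmeansK = 10L,
                           mergeCorrThreshold = 0.9, ageGridStep = 1,
                           randomSeed = 1L, weightingEnabled = TRUE,
                           fcMode = c("endpoints", "amplitude"),
                           kmeansRestarts = 5L) {
    fcMode <- match.arg(fcMode)
    methods::new("AnalysisConfig",
        fdrThreshold = as.numeric(fdrThreshold),
        absFcThreshold = as.numeric(absFcThreshold),
        windowHalfwidth = as.numeric(windowHalfwidth),
        kmeansK = as.integer(kmeansK),
        mergeCorrThreshold = as.numeric(mergeCorrThreshold),
        ageGridStep = as.numeric(ageGridStep),
        randomSeed = as.integer(randomSeed),
        weightingEnabled = as.logical(weightingEnabled),
        fcMode = fcMode,
        kmeansRestarts = as.integer(kmeansRestarts))
}

#' Load an analysis configuration from a key-value file
#'
#' Accepts lines of the form `key = value`, `key: value` or `key<TAB>value`;
#' blank lines and `#` comments are ignored. Missing keys take their
#' defaults; unknown keys raise an error, as do out-of-range values.
#' Keys use snake_case: `fdr_threshold`, `abs_fc_threshold`,
#' `window_halfwidth`, `kmeans_k`, `merge_corr_threshold`, `age_grid_step`,
#' `random_seed`, `weighting_enabled`, `fc_mode`, `kmeans_restarts`.
#'
#' @param path path to the config file.
#' @return An [AnalysisConfig-class] object.
#' @export
loadConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    keymap <- c(fdr_threshold = "fdrThreshold",
                abs_fc_threshold = "absFcThreshold",
                window_halfwidth = "windowHalfwidth",
                kmeans_k = "kmeansK",
                merge_corr_threshold = "mergeCorrThreshold",
                age_grid_step = "ageGridStep",
                random_seed = "randomSeed",
                weighting_enabled = "weightingEnabled",
                fc_mode = "fcMode",
                kmeans_restarts = "kmeansRestarts")
    args <- list()
    for (ln in lines) {
        m <- regmatches(ln, regexec("^([A-Za-z_]+)[ \t:=]+(.+)$", ln))[[1]]
        if (length(m) != 3L)
            stop("cannot parse config line: '", ln, "'")
        key <- m[2]; val <- trimws(m[3])
        if (!key %in% names(keymap))
            stop("unknown config key: '", key, "'")
        arg <- keymap[[key]]
        args[[arg]] <- switch(arg,
            fcMode = val,
            weightingEnabled = as.logical(val),
            kmeansK = , kmeansRestarts = , randomSeed = as.integer(val),
            as.numeric(val))
        if (is.na(args[[arg]]))
            stop("invalid value for config key '", key, "': '", val, "'")
    }
    tryCatch(do.call(analysisConfig, args), error = function(e)
        stop("invalid configuration in '", path, "': ", conditionMessage(e)))
}

#' Read an expression matrix and its sample metadata
#'
#' The expression file is a TSV with a `probe_id` first column and one column
#' per sample; the metadata TSV has columns `sample_id`, `age` and optionally
#' `sex`. Samples are keyed by id, not position: expression columns are
#' reordered to the metadata order, and a mismatch in either direction is an
#' error naming the offending ids.
#'
#' @param path expression TSV.
#' @param metadataPath sample metadata TSV.
#' @param detectionPath optional detection p-value TSV of the same layout as
#'   the expression file.
#' @return An [AgeExpressionSet-class].
#' @export
readExpressionMatrix <- function(path, metadataPath, detectionPath = NULL) {
    expr <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (colnames(expr)[1] != "probe_id")
        stop("first column of the expression file must be 'probe_id'")
    probes <- as.character(expr$probe_id)
    if (anyDuplicated(probes))
        stop("duplicated probe ids in expression file: ",
             paste(unique(probes[duplicated(probes)]), collapse = ", "))
    values <- as.matrix(expr[, -1, drop = FALSE])
    rownames(values) <- probes
    meta <- utils::read.delim(metadataPath, check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (!all(c("sample_id", "age") %in% colnames(meta)))
        stop("metadata must contain 'sample_id' and 'age' columns")
    sids <- as.character(meta$sample_id)
    missingInMeta <- setdiff(colnames(values), sids)
    missingInExpr <- setdiff(sids, colnames(values))
    if (length(missingInMeta) || length(missingInExpr))
        stop("sample id mismatch between expression and metadata",
             if (length(missingInMeta))
                 paste0("; absent from metadata: ",
                        paste(missingInMeta, collapse = ", ")),
             if (length(missingInExpr))
                 paste0("; absent from expression: ",
                        paste(missingInExpr, collapse = ", ")))
    if (!is.numeric(meta$age) || any(is.na(meta$age)))
        stop("metadata ages must be numeric and non-missing")
    values <- values[, sids, drop = FALSE]
    detection <- NULL
    if (!is.null(detectionPath)) {
        det <- utils::read.delim(detectionPath, check.names = FALSE,
                                 stringsAsFactors = FALSE)
        detection <- as.matrix(det[, -1, drop = FALSE])
        rownames(detection) <- as.character(det$probe_id)
        if (!identical(dim(detection), dim(values)))
            stop("detection matrix shape differs from expression matrix")
        detection <- detection[probes, sids, drop = FALSE]
    }
    AgeExpressionSet(values, ages = meta$age, sex = meta$sex,
                     detection = detection)
}

#' Read a probe-to-gene annotation table
#'
#' TSV with columns `probe_id` and `gene_id`; many probes may map to one
#' gene, but each probe may appear at most once.
#'
#' @param path annotation TSV.
#' @return A [S4Vectors::DataFrame] with columns `probe_id`, `gene_id`.
#' @export
readAnnotation <- function(path) {
    ann <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!all(c("probe_id", "gene_id") %in% colnames(ann)))
        stop("annotation must contain 'probe_id' and 'gene_id' columns")
    if (anyDuplicated(ann$probe_id))
        stop("duplicated probe ids in annotation: ",
             paste(unique(ann$probe_id[duplicated(ann$probe_id)]),
                   collapse = ", "))
    S4Vectors::DataFrame(probe_id = ann$probe_id, gene_id = ann$gene_id)
}

#' Attach gene annotation to a dataset's probes
#'
#' Probes absent from the annotation table (or annotated with an empty gene
#' id) are flagged unannotated; they still take part in fitting and
#' clustering and are only dropped from gene-level comparisons.
#'
#' @param dataset an [AgeExpressionSet-class].
#' @param annotation a DataFrame/data.frame with `probe_id`, `gene_id`.
#' @return A [S4Vectors::DataFrame] with one row per dataset probe and
#'   columns `probe_id`, `gene_id` (NA when unannotated), `annotated`; its
#'   [S4Vectors::metadata()] records the `unannotatedFraction`.
#' @export
joinAnnotation <- function(dataset, annotation) {
    probes <- rownames(dataset)
    idx <- match(probes, as.character(annotation$probe_id))
    gene <- as.character(annotation$gene_id)[idx]
    gene[!is.na(gene) & !nzchar(gene)] <- NA_character_
    out <- S4Vectors::DataFrame(probe_id = probes, gene_id = gene,
                                annotated = !is.na(gene))
    S4Vectors::metadata(out) <- list(
        unannotatedFraction = mean(is.na(gene)))
    out
}

#' Write the per-probe results table
#'
#' One row per fitted probe with columns `probe_id`, `alpha`, `beta`,
#' `gamma`, `pvalue`, `qvalue`, `fold_change`, `direction`, `cluster_id`
#' (empty when no clustering is supplied). Numeric fields are written with
#' 17 significant digits so a write/read cycle is lossless.
#'
#' @param fits a [ProbeFitResults-class].
#' @param clusters optional [TrendClusterSet-class] supplying cluster ids.
#' @param path output TSV path.
#' @param header optional comment lines (each prefixed `# `) written before
#'   the table, e.g. the config echo.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(fits, clusters = NULL, path, header = NULL) {
    tab <- fitTable(fits)
    cl <- rep(NA_integer_, nrow(tab))
    if (!is.null(clusters))
        cl <- unname(clusterAssignments(clusters)[tab$probe_id])
    df <- data.frame(probe_id = tab$probe_id,
                     alpha = .fmtNum(tab$alpha), beta = .fmtNum(tab$beta),
                     gamma = .fmtNum(tab$gamma), pvalue = .fmtNum(tab$pvalue),
                     qvalue = .fmtNum(tab$qvalue),
                     fold_change = .fmtNum(tab$fold_change),
                     direction = tab$direction,
                     cluster_id = ifelse(is.na(cl), "", as.character(cl)),
                     stringsAsFactors = FALSE, check.names = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header))
        writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read back a results table written by [writeResultsTable()]
#'
#' @param path results TSV.
#' @return A data.frame with the written columns, numerics restored.
#' @export
readResultsTable <- function(path) {
    utils::read.delim(path, comment.char = "#", check.names = FALSE,
                      stringsAsFactors = FALSE,
                      colClasses = c(probe_id = "character"))
}

#' Write an expression dataset to the canonical TSV pair
#'
#' Inverse of [readExpressionMatrix()]: writes `<prefix>_expression.tsv`,
#' `<prefix>_metadata.tsv` and, if present, `<prefix>_detection.tsv`.
#'
#' @param dataset an [AgeExpressionSet-class].
#' @param prefix file path prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeExpressionMatrix <- function(dataset, prefix) {
    values <- exprsValues(dataset)
    ef <- paste0(prefix, "_expression.tsv")
    mf <- paste0(prefix, "_metadata.tsv")
    em <- cbind(data.frame(probe_id = rownames(values),
                           stringsAsFactors = FALSE), .fmtMat(values))
    utils::write.table(em, ef, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- SummarizedExperiment::colData(dataset)
    md <- data.frame(sample_id = rownames(cd), age = .fmtNum(cd$age),
                     stringsAsFactors = FALSE, check.names = FALSE)
    if ("sex" %in% colnames(cd)) md$sex <- cd$sex
    utils::write.table(md, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(expression = ef, metadata = mf)
    if (!is.null(detectionP(dataset))) {
        df <- paste0(prefix, "_detection.tsv")
        dm <- cbind(data.frame(probe_id = rownames(values),
                               stringsAsFactors = FALSE),
                    .fmtMat(detectionP(dataset)))
        utils::write.table(dm, df, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, detection = df)
    }
    invisible(paths)
}
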