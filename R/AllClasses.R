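#' AgeExpressionSet: a cross-sectional expression cohort
#'
#' Container for a probe-by-sample matrix of log2 intensities together with
#' per-sample age (in years) and optional sex, plus an optional matrix of
#' detection p-values of the same shape. Extends
#' \linkS4class{SummarizedExperiment}: the expression matrix lives in the
#' `"exprs"` assay, detection p-values (if present) in the `"detection"`
#' assay, and age/sex in `colData`.
#'
#' Validity requires unique probe and sample identifiers, finite expression
#' values, finite positive ages, and detection p-values in \[0, 1\].
#'
#' @seealso [AgeExpressionSet()] for the constructor, [ages()],
#'   [detectionP()].
#' @export
setClass("AgeExpressionSet", contains = "SummarizedExperiment")

setValidity("AgeExpressionSet", function(object) {
    msg <- character(0)
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is required")
    if (is.null(rownames(object)) || is.null(colnames(object)))
        msg <- c(msg, "probe and sample identifiers are required")
    else {
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "duplicated probe ids: ",
                     paste(unique(rownames(object)[duplicated(rownames(object))]),
                           collapse = ", "))
        if (anyDuplicated(colnames(object)))
            msg <- c(msg, "duplicated sample ids: ",
                     paste(unique(colnames(object)[duplicated(colnames(object))]),
                           collapse = ", "))
    }
    if (!"age" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain an 'age' column")
    else {
        a <- SummarizedExperiment::colData(object)$age
        if (!is.numeric(a) || any(!is.finite(a)) || any(a <= 0))
            msg <- c(msg, "ages must be finite and positive")
    }
    if ("exprs" %in% SummarizedExperiment::assayNames(object) &&
        any(!is.finite(SummarizedExperiment::assay(object, "exprs"))))
        msg <- c(msg, "expression values must all be finite")
    if ("detection" %in% SummarizedExperiment::assayNames(object)) {
        d <- SummarizedExperiment::assay(object, "detection")
        if (any(!is.finite(d)) || any(d < 0) || any(d > 1))
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SampleWeights: moving-window sample weights
#'
#' Per-sample neighbourhood counts `N_i` (number of cohort members, including
#' the sample itself, whose age lies within `halfwidth` years) and the
#' corresponding weights `w_i = 1/N_i`.
#'
#' @slot counts integer vector of neighbourhood counts, one per sample.
#' @slot weights numeric vector, exactly `1/counts`.
#' @slot halfwidth age window half-width in years.
#' @slot sampleIds sample identifiers, aligned with `counts`.
#' @export
setClass("SampleWeights",
    representation(counts = "integer", weights = "numeric",
                   halfwidth = "numeric", sampleIds = "character"))

setValidity("SampleWeights", function(object) {
    msg <- character(0)
    if (length(object@counts) != length(object@weights))
        msg <- c(msg, "counts and weights must be parallel")
    if (any(object@counts < 1L))
        msg <- c(msg, "every neighbourhood count must be >= 1")
    if (!identical(object@weights, 1 / as.numeric(object@counts)))
        msg <- c(msg, "weights must equal 1/counts exactly")
    if (length(object@halfwidth) != 1L || object@halfwidth <= 0)
        msg <- c(msg, "halfwidth must be a single positive number")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' AnalysisConfig: tunable parameters of the pipeline
#'
#' @slot fdrThreshold Benjamini-Hochberg FDR cut-off (default 0.05).
#' @slot absFcThreshold minimum absolute fold change kept (default 1.2).
#' @slot windowHalfwidth sample-weighting window half-width in years
#'   (default 5, i.e. an 11-year closed window at integer ages).
#' @slot kmeansK number of K-means clusters before merging (default 10).
#' @slot mergeCorrThreshold signed centroid correlation at or above which
#'   clusters are merged (default 0.9).
#' @slot ageGridStep spacing of the age grid in years (default 1).
#' @slot randomSeed seed for every stochastic step.
#' @slot weightingEnabled whether moving-window weights enter the fits.
#' @slot fcMode fold-change mode, "endpoints" or "amplitude".
#' @slot kmeansRestarts number of K-means restarts (default 5).
#' @export
setClass("AnalysisConfig",
    representation(fdrThreshold = "numeric", absFcThreshold = "numeric",
                   windowHalfwidth = "numeric", kmeansK = "integer",
                   mergeCorrThreshold = "numeric", ageGridStep = "numeric",
                   randomSeed = "integer", weightingEnabled = "logical",
                   fcMode = "character", kmeansRestarts = "integer"))

setValidity("AnalysisConfig", function(object) {
    msg <- character(0)
    if (object@fdrThreshold <= 0 || object@fdrThreshold >= 1)
        msg <- c(msg, "fdr_threshold must lie strictly between 0 and 1")
    if (object@absFcThreshold < 1)
        msg <- c(msg, "abs_fc_threshold must be >= 1")
    if (object@windowHalfwidth <= 0)
        msg <- c(msg, "window_halfwidth must be > 0")
    if (object@kmeansK < 2L)
        msg <- c(msg, "kmeans_k must be >= 2")
    if (object@mergeCorrThreshold < -1 || object@mergeCorrThreshold > 1)
        msg <- c(msg, "merge_corr_threshold must lie in [-1, 1]")
    if (object@ageGridStep <= 0)
        msg <- c(msg, "age_grid_step must be > 0")
    if (!object@fcMode %in% c("endpoints", "amplitude"))
        msg <- c(msg, "fc_mode must be 'endpoints' or 'amplitude'")
    if (object@kmeansRestarts < 1L)
        msg <- c(msg, "kmeans_restarts must be >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' ProbeFitResults: per-probe quadratic age-trend fits
#'
#' Holds the regression coefficients (intercept `alpha`, linear `beta`,
#' quadratic `gamma`), the F-test p-value against the intercept-only null,
#' the BH q-value, the signed fold change with its direction, and the
#' smoothed trajectory of every probe evaluated on a common age grid.
#'
#' @slot table a [S4Vectors::DataFrame] with one row per probe and columns
#'   `probe_id`, `alpha`, `beta`, `gamma`, `pvalue`, `qvalue`, `fold_change`,
#'   `direction`, `perfect_fit`.
#' @slot smoothed probe-by-grid matrix of fitted trajectories.
#' @slot ageGrid the age grid (years) the trajectories are evaluated on.
#' @slot fcMode fold-change mode used ("endpoints" or "amplitude").
#' @slot weighted whether sample weights entered the fits.
#' @export
setClass("ProbeFitResults",
    representation(table = "DataFrame", smoothed = "matrix",
                   ageGrid = "numeric", fcMode = "character",
                   weighted = "logical"))

setValidity("ProbeFitResults", function(object) {
    msg <- character(0)
    need <- c("probe_id", "alpha", "beta", "gamma", "pvalue", "qvalue",
              "fold_change", "direction")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, "fit table is missing columns")
    if (nrow(object@smoothed) != nrow(object@table))
        msg <- c(msg, "smoothed matrix and fit table disagree on probe count")
    if (ncol(object@smoothed) != length(object@ageGrid))
        msg <- c(msg, "smoothed matrix and age grid disagree")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' TrendClusterSet: clustered standardized trajectories
#'
#' @slot assignments integer cluster index per probe (NA after singleton
#'   removal), named by probe id.
#' @slot centroids cluster-by-grid matrix of centroid trajectories.
#' @slot sizes member count per cluster.
#' @slot inclinations "positive", "negative" or "ambiguous" per cluster
#'   (NA before [labelInclinations()]).
#' @slot trajectories the probe-by-grid matrix that was clustered.
#' @slot ageGrid the age grid in years.
#' @slot metric "euclidean" or "abscor".
#' @slot seed the seed the partition was computed under.
#' @export
setClass("TrendClusterSet",
    representation(assignments = "integer", centroids = "matrix",
                   sizes = "integer", inclinations = "character",
                   trajectories = "matrix", ageGrid = "numeric",
                   metric = "character", seed = "integer"))

#' AgePosition: the conjunction point of opposite trajectory groups
#'
#' @slot age the detected age-position in years (NA when no crossing exists).
#' @slot decade integer decade, `floor(age/10) + 1` (the seventh decade spans
#'   ages 60-69).
#' @slot method "trajectory-crossing" or "quadratic-vertex".
#' @slot clusterId index of the supporting absolute-correlation cluster.
#' @slot secondary ages of any secondary crossings.
#' @slot supportSizes sizes of the two sign groups the crossing is formed
#'   from (positive group first).
#' @slot note diagnostic message when no age-position is found.
#' @export
setClass("AgePosition",
    representation(age = "numeric", decade = "integer", method = "character",
                   clusterId = "integer", secondary = "numeric",
                   supportSizes = "integer", note = "character"))

#' OverlapResult: cross-dataset significant-set overlap
#'
#' @slot setA,setB named integer vectors mapping gene (or probe) id to
#'   direction (+1/-1).
#' @slot shared ids present in both sets.
#' @slot concordant ids with the same direction in both sets.
#' @slot discordant ids with opposite directions.
#' @slot reference which set ("A" or "B") the percentage denominator uses.
#' @slot overlapPercent overlap count as a percentage of the reference set
#'   size (NA when the reference set is empty).
#' @export
setClass("OverlapResult",
    representation(setA = "integer", setB = "integer", shared = "character",
                   concordant = "character", discordant = "character",
                   reference = "character", overlapPercent = "numeric"))
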