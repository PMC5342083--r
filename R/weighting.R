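#' @include AllClasses.R AllGenerics.R
NULL

#' Moving-window neighbourhood counts
#'
#' For each sample, counts the cohort members (including the sample itself)
#' whose age lies within `halfwidth` years: `N_i = #{j : |age_j - age_i| <=
#' halfwidth}`. The window is closed, so the default half-width of 5 years
#' spans an 11-year window at integer ages.
#'
#' @param ages numeric vector of ages in years.
#' @param halfwidth window half-width in years (default 5).
#' @return Integer vector of counts, one per sample.
#' @export
neighborhoodCounts <- function(ages, halfwidth = 5) {
    if (length(ages) == 0L)
        stop("age vector is empty")
    if (any(!is.finite(ages)))
        stop("ages must be finite")
    if (halfwidth <= 0)
        stop("halfwidth must be > 0")
    # O(n log n): for sorted ages the window is a contiguous run
    o <- order(ages)
    s <- ages[o]
    n <- length(s)
    lo <- findInterval(s - halfwidth, s, left.open = TRUE) + 1L
    hi <- findInterval(s + halfwidth, s)
    counts <- integer(n)
    counts[o] <- hi - lo + 1L
    counts
}

#' Inverse-proportional sample weights
#'
#' Converts neighbourhood counts into weights `w_i = 1/N_i`, so samples from
#' over-represented age regions are down-weighted and samples from sparse
#' regions up-weighted. Weights are deliberately not renormalized: every
#' downstream fit statistic is invariant to a global weight scale.
#'
#' @param counts integer neighbourhood counts (all >= 1).
#' @param halfwidth the window half-width the counts were computed with
#'   (recorded in the result).
#' @param sampleIds optional sample identifiers.
#' @return A [SampleWeights-class] object.
#' @export
computeWeights <- function(counts, halfwidth = 5, sampleIds = character(0)) {
    if (length(counts) == 0L)
        stop("no counts supplied")
    if (any(!is.finite(counts)) || any(counts < 1))
        stop("all neighbourhood counts must be >= 1")
    counts <- as.integer(counts)
    methods::new("SampleWeights", counts = counts, weights = 1 / as.numeric(counts),
                 halfwidth = as.numeric(halfwidth),
                 sampleIds = as.character(sampleIds))
}

#' Compute moving-window weights for a cohort
#'
#' Convenience wrapper: [neighborhoodCounts()] then [computeWeights()].
#'
#' @param x an [AgeExpressionSet-class] or a numeric vector of ages.
#' @param halfwidth window half-width in years (default 5).
#' @return A [SampleWeights-class] object.
#' @export
cohortWeights <- function(x, halfwidth = 5) {
    if (methods::is(x, "AgeExpressionSet")) {
        ids <- colnames(x)
        a <- ages(x)
    } else {
        ids <- names(x)
        if (is.null(ids)) ids <- character(0)
        a <- as.numeric(x)
    }
    computeWeights(neighborhoodCounts(a, halfwidth), halfwidth, ids)
}

#' @describeIn computeWeights neighbourhood counts.
#' @param x a `SampleWeights` object.
#' @export
setMethod("sampleCounts", "SampleWeights", function(x) x@counts)

#' @describeIn computeWeights the weights `1/N_i`.
#' @export
setMethod("sampleWeights", "SampleWeights", function(x) x@weights)

setMethod("show", "SampleWeights", function(object) {
    cat("SampleWeights for", length(object@counts), "samples",
        sprintf("(halfwidth %g years)\n", object@halfwidth))
    cat(sprintf("  counts %d-%d, weights %.4g-%.4g\n",
                min(object@counts), max(object@counts),
                min(object@weights), max(object@weights)))
    invisible(NULL)
})

#' Write the per-sample weight table
#'
#' @param weights a [SampleWeights-class].
#' @param ages ages aligned with the weights.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeWeightsTable <- function(weights, ages, path) {
    ids <- weights@sampleIds
    if (!length(ids)) ids <- paste0("sample_", seq_along(ages))
    df <- data.frame(sample_id = ids, age = .fmtNum(ages),
                     neighborhood_count = sampleCounts(weights),
                     weight = .fmtNum(sampleWeights(weights)),
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
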