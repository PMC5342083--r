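#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an AgeExpressionSet
#'
#' @param values probe-by-sample numeric matrix of log2 intensities, with
#'   probe ids as rownames and sample ids as colnames (supplied separately via
#'   `probeIds`/`sampleIds` if unnamed).
#' @param ages numeric vector of ages in years, one per sample.
#' @param sex optional per-sample factor or character vector.
#' @param detection optional probe-by-sample matrix of detection p-values,
#'   same shape as `values`.
#' @param probeIds,sampleIds identifiers used when `values` is unnamed.
#'
#' @return An [AgeExpressionSet-class] object.
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
#' aes <- AgeExpressionSet(m, ages = c(50, 60, 70, 80))
#' ages(aes)
#' @export
AgeExpressionSet <- function(values, ages, sex = NULL, detection = NULL,
                             probeIds = rownames(values),
                             sampleIds = colnames(values)) {
    values <- as.matrix(values)
    if (is.null(probeIds) || is.null(sampleIds))
        stop("probe and sample identifiers are required")
    storage.mode(values) <- "double"
    dimnames(values) <- list(as.character(probeIds), as.character(sampleIds))
    if (length(ages) != ncol(values))
        stop("need one age per sample: got ", length(ages), " ages for ",
             ncol(values), " samples")
    cd <- S4Vectors::DataFrame(age = as.numeric(ages), row.names = sampleIds)
    if (!is.null(sex)) cd$sex <- sex
    assays <- list(exprs = values)
    if (!is.null(detection)) {
        detection <- as.matrix(detection)
        if (!all(dim(detection) == dim(values)))
            stop("detection matrix must have the same shape as the ",
                 "expression matrix")
        dimnames(detection) <- dimnames(values)
        assays$detection <- detection
    }
    se <- SummarizedExperiment::SummarizedExperiment(assays = assays,
                                                     colData = cd)
    methods::new("AgeExpressionSet", se)
}

#' @describeIn AgeExpressionSet per-sample ages in years.
#' @param x an `AgeExpressionSet`.
#' @export
setMethod("ages", "AgeExpressionSet", function(x)
    SummarizedExperiment::colData(x)$age)

#' @describeIn AgeExpressionSet detection p-value matrix, or NULL.
#' @export
setMethod("detectionP", "AgeExpressionSet", function(x) {
    if ("detection" %in% SummarizedExperiment::assayNames(x))
        SummarizedExperiment::assay(x, "detection")
    else NULL
})

#' Expression values of an AgeExpressionSet
#'
#' Convenience accessor for the `"exprs"` assay.
#' @param x an `AgeExpressionSet`.
#' @return probe-by-sample numeric matrix.
#' @export
exprsValues <- function(x) SummarizedExperiment::assay(x, "exprs")

setMethod("show", "AgeExpressionSet", function(object) {
    cat("AgeExpressionSet with", nrow(object), "probes and", ncol(object),
        "samples\n")
    a <- ages(object)
    cat(sprintf("  age range %.1f-%.1f years (median %.1f)\n",
                min(a), max(a), stats::median(a)))
    if (!is.null(detectionP(object))) cat("  detection p-values present\n")
    invisible(NULL)
})
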