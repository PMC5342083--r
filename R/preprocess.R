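#' @include AllClasses.R AllGenerics.R
NULL

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' row-wise mean of the per-column sorted values, preserving within-column
#' rank order. Ties receive the mean of the reference values at the tied
#' ranks, so tied entries stay tied. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param values probe-by-sample numeric matrix with at least two columns.
#' @return Matrix of the same shape, quantile-normalized.
#' @export
quantileNormalize <- function(values) {
    values <- as.matrix(values)
    if (ncol(values) < 2L)
        stop("quantile normalization needs at least 2 samples")
    if (any(!is.finite(values)))
        stop("expression values must be finite")
    out <- limma::normalizeQuantiles(values, ties = TRUE)
    dimnames(out) <- dimnames(values)
    out
}

#' Elementwise log2 transform
#'
#' @param values matrix of strictly positive intensities.
#' @return `log2(values)`.
#' @export
log2Transform <- function(values) {
    values <- as.matrix(values)
    bad <- which(values <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
        lab <- if (!is.null(rownames(values)))
            paste0(rownames(values)[bad[1, 1]], "/",
                   colnames(values)[bad[1, 2]])
        else paste0("[", bad[1, 1], ",", bad[1, 2], "]")
        stop("nonpositive intensity at ", lab,
             " cannot be log2-transformed")
    }
    log2(values)
}

#' Centre probe and sample means to zero
#'
#' Subtracts each row (probe) mean, then each column (sample) mean; the
#' result has both margins zero. The operation is idempotent and linear.
#'
#' @param values numeric matrix.
#' @return Double-centred matrix of the same shape.
#' @export
doubleCenter <- function(values) {
    values <- as.matrix(values)
    values <- values - rowMeans(values)
    sweep(values, 2L, colMeans(values))
}

#' Filter probes by detection p-values
#'
#' Keeps exactly the probes whose detection p-value is below `pCut` in
#' strictly more than `sampleFrac` of samples (the "more than 10% of all
#' samples" convention; a probe detected in exactly 10% of samples is
#' removed). Surviving expression values are untouched.
#'
#' @param dataset an [AgeExpressionSet-class] carrying a detection assay.
#' @param pCut detection p-value cut-off (default 0.05).
#' @param sampleFrac strict fraction-of-samples threshold (default 0.10).
#' @return The filtered dataset; the ids of removed probes are available via
#'   `metadata(x)$removedProbes`.
#' @export
detectionFilter <- function(dataset, pCut = 0.05, sampleFrac = 0.10) {
    dp <- detectionP(dataset)
    if (is.null(dp))
        stop("no detection p-values present; skip the detection filter ",
             "for this dataset")
    frac <- rowMeans(dp < pCut)
    keep <- frac > sampleFrac
    out <- dataset[keep, ]
    S4Vectors::metadata(out)$removedProbes <- rownames(dataset)[!keep]
    out
}

#' PCA-based sample outlier screen
#'
#' Projects samples onto the first `nComponents` principal components of the
#' sample-by-probe centred matrix (via SVD, [stats::prcomp()]) and flags
#' samples whose score on any retained component lies more than `sdLimit`
#' standard deviations from that component's mean. The screen is advisory:
#' no samples are removed.
#'
#' @param values probe-by-sample matrix (or an [AgeExpressionSet-class]).
#' @param nComponents number of leading components examined (default 2).
#' @param sdLimit flagging threshold in component standard deviations
#'   (default 4).
#' @return A list with `flagged` (logical per sample), `scores`
#'   (sample-by-component matrix) and `sdev` (component standard deviations).
#' @export
pcaOutlierScreen <- function(values, nComponents = 2L, sdLimit = 4) {
    if (methods::is(values, "AgeExpressionSet"))
        values <- exprsValues(values)
    values <- as.matrix(values)
    if (ncol(values) < 3L)
        stop("PCA screening needs at least 3 samples")
    pc <- stats::prcomp(t(values), center = TRUE, scale. = FALSE)
    k <- min(nComponents, ncol(pc$x))
    scores <- pc$x[, seq_len(k), drop = FALSE]
    sdev <- pc$sdev[seq_len(k)]
    # prcomp scores are mean-zero by construction
    flagged <- rep(FALSE, nrow(scores))
    for (j in seq_len(k)) {
        if (sdev[j] > 0)
            flagged <- flagged | abs(scores[, j]) > sdLimit * sdev[j]
    }
    names(flagged) <- colnames(values)
    list(flagged = flagged, scores = scores, sdev = sdev)
}

#' Run the standard pre-processing chain on a dataset
#'
#' Optionally quantile-normalizes and log2-transforms, applies the detection
#' prefilter (off by default, mirroring a cohort deposited without
#' prefiltering), runs the advisory PCA screen, and double-centres. Order:
#' normalize, transform, detection filter, centre.
#'
#' @param dataset an [AgeExpressionSet-class].
#' @param quantile,log2,detection,center stage switches.
#' @param pCut,sampleFrac detection filter parameters.
#' @param pcaScreen run the advisory outlier screen and record its report.
#' @return The processed dataset; `metadata()` carries a `preprocessReport`.
#' @export
preprocessDataset <- function(dataset, quantile = FALSE, log2 = FALSE,
                              detection = FALSE, center = TRUE,
                              pCut = 0.05, sampleFrac = 0.10,
                              pcaScreen = TRUE) {
    report <- list(probesIn = nrow(dataset))
    values <- exprsValues(dataset)
    if (quantile) values <- quantileNormalize(values)
    if (log2) values <- log2Transform(values)
    SummarizedExperiment::assay(dataset, "exprs") <- values
    if (detection) {
        dataset <- detectionFilter(dataset, pCut, sampleFrac)
        report$removedProbes <- S4Vectors::metadata(dataset)$removedProbes
    }
    if (pcaScreen) {
        scr <- pcaOutlierScreen(exprsValues(dataset))
        report$flaggedSamples <- names(scr$flagged)[scr$flagged]
    }
    if (center)
        SummarizedExperiment::assay(dataset, "exprs") <-
            doubleCenter(exprsValues(dataset))
    report$probesOut <- nrow(dataset)
    S4Vectors::metadata(dataset)$preprocessReport <- report
    dataset
}
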