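#' @include AllClasses.R AllGenerics.R
NULL

# Weighted quadratic age-trend fitting and filtering.
#
# All probes of a cohort share one design matrix X = [1, x, x^2] and one
# weight vector, so the whole cohort is fitted in a single QR factorization
# of sqrt(w)*X. Supplied weights are normalized by their maximum before
# entering the loss: every reported statistic is invariant to a global
# weight scale, and an equal-weight run then takes the bit-identical code
# path as an unweighted run.

.resolveWeights <- function(weights, n) {
    if (is.null(weights)) return(rep(1, n))
    if (methods::is(weights, "SampleWeights")) weights <- sampleWeights(weights)
    weights <- as.numeric(weights)
    if (length(weights) != n)
        stop("need one weight per sample")
    if (any(!is.finite(weights)) || any(weights <= 0))
        stop("weights must be finite and > 0")
    weights / max(weights)
}

# Core engine: Y is a samples-by-probes matrix.
.fitEngine <- function(Y, ages, weights = NULL) {
    n <- length(ages)
    if (nrow(Y) != n) stop("Y must have one row per sample")
    if (any(!is.finite(Y))) stop("expression values must be finite")
    if (length(unique(ages)) < 3L)
        stop("rank deficiency: need at least 3 distinct ages for a ",
             "quadratic fit")
    w <- .resolveWeights(weights, n)
    X <- cbind(1, ages, ages^2)
    sw <- sqrt(w)
    qrX <- qr(X * sw)
    if (qrX$rank < 3L)
        stop("rank deficiency: design matrix is singular")
    coef <- qr.coef(qrX, Y * sw)
    fitted <- X %*% coef
    res <- Y - fitted
    rss1 <- colSums(w * res * res)
    mu0 <- colSums(w * Y) / sum(w)
    dev0 <- Y - rep(1, n) %o% mu0
    rss0 <- colSums(w * dev0 * dev0)
    dimnames(coef) <- list(c("alpha", "beta", "gamma"), colnames(Y))
    list(coef = coef, residuals = res, rss1 = rss1, rss0 = rss0,
         n = n, weights = w)
}

#' Fit a weighted quadratic age trend to one probe
#'
#' Minimizes the weighted sum of squared residuals
#' `sum_j w_j (y_j - alpha - beta x_j - gamma x_j^2)^2`; with no weights this
#' is ordinary least squares. At least 4 samples and 3 distinct ages are
#' required.
#'
#' @param y per-sample log2 intensities.
#' @param ages per-sample ages in years.
#' @param weights optional [SampleWeights-class] or positive numeric vector.
#' @return List with `alpha`, `beta`, `gamma` and per-sample `residuals`.
#' @examples
#' x <- seq(40, 80, length.out = 20)
#' fit <- fitQuadratic(2 + 0.1 * x + 0.01 * x^2, x)
#' unlist(fit[c("alpha", "beta", "gamma")])
#' @export
fitQuadratic <- function(y, ages, weights = NULL) {
    if (length(y) != length(ages))
        stop("y and ages must be parallel")
    if (length(y) < 4L)
        stop("need at least 4 samples")
    eng <- .fitEngine(cbind(y), ages, weights)
    list(alpha = unname(eng$coef[1, 1]), beta = unname(eng$coef[2, 1]),
         gamma = unname(eng$coef[3, 1]), residuals = drop(eng$residuals))
}

#' Evaluate a quadratic trajectory on an age grid
#'
#' @param coefs list or numeric vector with `alpha`, `beta`, `gamma`.
#' @param ageGrid ascending ages (years) to evaluate at.
#' @return Fitted values `alpha + beta*x + gamma*x^2`.
#' @export
smoothTrajectory <- function(coefs, ageGrid) {
    coefs <- unname(unlist(coefs)[c("alpha", "beta", "gamma")])
    coefs[1] + coefs[2] * ageGrid + coefs[3] * ageGrid^2
}

#' F-test of age association for one probe
#'
#' Compares the intercept-only model to the quadratic model on the same
#' weights: `F = ((RSS0 - RSS1)/2) / (RSS1/(n-3))` with p from F(2, n-3),
#' using weighted residual sums of squares when weights are supplied. A
#' perfect fit (`RSS1` exactly 0) is reported as the smallest representable
#' positive p with attribute `perfect_fit = TRUE`.
#'
#' @inheritParams fitQuadratic
#' @return A p-value in \[0, 1\].
#' @export
ageAssociationTest <- function(y, ages, weights = NULL) {
    if (length(y) < 5L) stop("need at least 5 samples for the F-test")
    eng <- .fitEngine(cbind(y), ages, weights)
    p <- .fTestP(eng$rss0, eng$rss1, eng$n)
    pv <- p$pvalue[1]
    if (p$perfect[1]) attr(pv, "perfect_fit") <- TRUE
    pv
}

.fTestP <- function(rss0, rss1, n) {
    Fst <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
    pvalue <- stats::pf(Fst, 2, n - 3, lower.tail = FALSE)
    perfect <- rss1 == 0
    pvalue[perfect] <- .Machine$double.xmin
    list(pvalue = pvalue, perfect = perfect)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: on sorted p-values,
#' `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1 and mapped back to
#' input order. Monotone and never below the raw p-value.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(pvalues)
    if (m == 0L) return(numeric(0))
    o <- order(pvalues, decreasing = TRUE)
    q <- pmin(1, cummin(pvalues[o] * m / (m:1)))
    q[order(o)]
}

#' Fold change of a smoothed trajectory
#'
#' In `"endpoints"` mode the net change is the fitted value at the oldest
#' grid age minus the value at the youngest; `|FC| = 2^|delta|` (values are
#' log2 intensities) and the direction is `sign(delta)`. In `"amplitude"`
#' mode the magnitude uses the trajectory's max - min excursion while the
#' direction still comes from the endpoint difference (a symmetric quadratic
#' can have near-zero endpoint change but a large excursion). A flat
#' trajectory has |FC| = 1 and direction 0.
#'
#' @param trajectory fitted values on the age grid (log2 scale).
#' @param mode `"endpoints"` (default) or `"amplitude"`.
#' @return List with `fold_change` (signed; magnitude kept for direction 0),
#'   `direction` in `{-1, 0, +1}` and the `mode` used.
#' @export
foldChange <- function(trajectory, mode = c("endpoints", "amplitude")) {
    mode <- match.arg(mode)
    delta <- trajectory[length(trajectory)] - trajectory[1]
    magnitude <- switch(mode,
        endpoints = 2^abs(delta),
        amplitude = 2^(max(trajectory) - min(trajectory)))
    direction <- sign(delta)
    fc <- if (direction == 0) magnitude else direction * magnitude
    list(fold_change = unname(fc), direction = unname(direction),
         mode = mode)
}

#' Fit quadratic age trends to every probe of a cohort
#'
#' Vectorized over probes: one weighted quadratic fit, F-test, BH
#' adjustment and fold-change computation per probe, plus the smoothed
#' trajectory on an integer-year age grid spanning the observed range.
#'
#' @param dataset an [AgeExpressionSet-class].
#' @param weights optional [SampleWeights-class]; `NULL` for unweighted fits.
#' @param config an [AnalysisConfig-class] (supplies the grid step and
#'   fold-change mode).
#' @return A [ProbeFitResults-class].
#' @export
fitProbes <- function(dataset, weights = NULL, config = analysisConfig()) {
    a <- ages(dataset)
    Y <- t(exprsValues(dataset))
    eng <- .fitEngine(Y, a, weights)
    grid <- seq(floor(min(a)), ceiling(max(a)), by = config@ageGridStep)
    G <- cbind(1, grid, grid^2)
    smoothed <- t(G %*% eng$coef)            # probes x grid
    colnames(smoothed) <- as.character(grid)
    ft <- .fTestP(eng$rss0, eng$rss1, eng$n)
    q <- bhAdjust(ft$pvalue)
    delta <- smoothed[, ncol(smoothed)] - smoothed[, 1]
    direction <- sign(delta)
    magnitude <- switch(config@fcMode,
        endpoints = 2^abs(delta),
        amplitude = 2^(apply(smoothed, 1, max) - apply(smoothed, 1, min)))
    fc <- ifelse(direction == 0, magnitude, direction * magnitude)
    tab <- S4Vectors::DataFrame(
        probe_id = rownames(dataset),
        alpha = unname(eng$coef[1, ]), beta = unname(eng$coef[2, ]),
        gamma = unname(eng$coef[3, ]),
        pvalue = unname(ft$pvalue), qvalue = unname(q),
        fold_change = unname(fc), direction = as.integer(direction),
        perfect_fit = unname(ft$perfect))
    methods::new("ProbeFitResults", table = tab, smoothed = smoothed,
                 ageGrid = as.numeric(grid), fcMode = config@fcMode,
                 weighted = !is.null(weights))
}

#' @describeIn fitProbes the per-probe fit table.
#' @param x a `ProbeFitResults` object.
#' @export
setMethod("fitTable", "ProbeFitResults", function(x) x@table)

#' @describeIn fitProbes probe-by-grid matrix of smoothed trajectories.
#' @export
setMethod("smoothedTrajectories", "ProbeFitResults", function(x) x@smoothed)

#' @describeIn fitProbes the age grid of the smoothed trajectories.
#' @export
setMethod("ageGrid", "ProbeFitResults", function(x) x@ageGrid)

setMethod("show", "ProbeFitResults", function(object) {
    tab <- object@table
    cat("ProbeFitResults:", nrow(tab), "probes,",
        if (object@weighted) "weighted" else "unweighted",
        "quadratic fits\n")
    cat(sprintf("  age grid %g-%g years; fold-change mode '%s'\n",
                min(object@ageGrid), max(object@ageGrid), object@fcMode))
    cat(sprintf("  q < 0.05: %d probes; q < 0.05 & |FC| >= 1.2: %d probes\n",
                sum(tab$qvalue < 0.05),
                sum(tab$qvalue < 0.05 & abs(tab$fold_change) >= 1.2)))
    invisible(NULL)
})

#' Filter fitted probes by FDR and fold change
#'
#' Keeps probes with `qvalue < fdrThreshold` and `|fold_change| >=
#' absFcThreshold` (the boundary fold change is kept). The summary reports
#' the volcano-plot partition: probes passing the FDR filter alone and
#' probes passing both.
#'
#' @param fits a [ProbeFitResults-class].
#' @param fdrThreshold FDR cut-off (default 0.05).
#' @param absFcThreshold minimum absolute fold change (default 1.2).
#' @return List with `fits` (a `ProbeFitResults` restricted to the
#'   significant probes), `summary` (counts) and `category` (per input probe:
#'   `"ns"`, `"fdr"`, or `"fdr_fc"`).
#' @export
filterProbes <- function(fits, fdrThreshold = 0.05, absFcThreshold = 1.2) {
    tab <- fitTable(fits)
    passQ <- tab$qvalue < fdrThreshold
    passF <- abs(tab$fold_change) >= absFcThreshold
    keep <- passQ & passF
    category <- ifelse(keep, "fdr_fc", ifelse(passQ, "fdr", "ns"))
    sub <- methods::new("ProbeFitResults",
                        table = tab[keep, , drop = FALSE],
                        smoothed = fits@smoothed[keep, , drop = FALSE],
                        ageGrid = fits@ageGrid, fcMode = fits@fcMode,
                        weighted = fits@weighted)
    list(fits = sub,
         summary = list(nTotal = nrow(tab), nFDR = sum(passQ),
                        nFDRFC = sum(keep),
                        fdrThreshold = fdrThreshold,
                        absFcThreshold = absFcThreshold),
         category = category)
}

#' Tabulate regulation directions of significant probes
#'
#' @param fits a [ProbeFitResults-class] (typically the filtered set).
#' @return List with `positive`, `negative`, `zero` and `total` counts.
#' @export
tabulateDirections <- function(fits) {
    d <- fitTable(fits)$direction
    list(positive = sum(d > 0), negative = sum(d < 0), zero = sum(d == 0),
         total = length(d))
}

#' Volcano-plot table
#'
#' Per-probe `log2fc`, `minus_log10_p` and the filter `category` matching
#' the published volcano partition.
#'
#' @param fits a [ProbeFitResults-class].
#' @param fdrThreshold,absFcThreshold filter thresholds.
#' @return A data.frame with one row per probe.
#' @export
volcanoTable <- function(fits, fdrThreshold = 0.05, absFcThreshold = 1.2) {
    tab <- fitTable(fits)
    fl <- filterProbes(fits, fdrThreshold, absFcThreshold)
    data.frame(probe_id = tab$probe_id,
               log2fc = sign(tab$fold_change) * log2(abs(tab$fold_change)),
               minus_log10_p = -log10(pmax(tab$pvalue,
                                           .Machine$double.xmin)),
               category = fl$category, stringsAsFactors = FALSE)
}
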