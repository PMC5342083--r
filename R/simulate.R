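#' @include AllClasses.R AllGenerics.R
NULL

# Synthetic cross-sectional cohorts with known ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# a cohort with a possibly skewed age distribution, per-probe mean
# trajectories drawn from a small set of archetypes whose change
# concentrates at a planted change-point age, and homoscedastic Gaussian
# noise on the log2 scale.

.ARCHETYPES <- c("null", "linear-up", "linear-down", "hinge-up",
                 "hinge-down", "quadratic")

#' Specify a synthetic cohort
#'
#' @param n number of samples (>= 10).
#' @param ageRange two ages, `c(lo, hi)` in years.
#' @param ageDist `"uniform"` or `"skewed"`.
#' @param skew skew parameter (>= 0). Skewed ages are drawn from a
#'   right-skewed Beta(1, 1 + skew) family rescaled to the age range, so the
#'   sample skewness is positive for `skew > 0` and the mode sits at the
#'   young end (under-representation of the elderly); `skew = 0` recovers
#'   the uniform distribution.
#' @param nProbes number of probes.
#' @param fracSignal fraction of non-null probes.
#' @param archetypeMix named non-null archetype mixture summing to 1 over
#'   `linear-up`, `linear-down`, `hinge-up`, `hinge-down`, `quadratic`.
#' @param changePoint hinge/vertex age in years (must lie in the age range).
#' @param delta total log2 change of a non-null probe over the age range.
#' @param noiseSd residual SD in log2 units.
#' @param baselineMean,baselineSd per-probe baseline log2 intensity
#'   distribution.
#' @param detection generate a detection p-value matrix.
#' @param fracUnexpressed fraction of probes simulated as unexpressed
#'   (uniform detection p; only used when `detection = TRUE`).
#' @param seed generator seed.
#' @return A validated list of class `CohortSpec`.
#' @export
cohortSpec <- function(n = 762, ageRange = c(46, 89),
                       ageDist = c("skewed", "uniform"), skew = 2,
                       nProbes = 1000, fracSignal = 0.2,
                       archetypeMix = c("linear-up" = 0.15,
                                        "linear-down" = 0.15,
                                        "hinge-up" = 0.3, "hinge-down" = 0.3,
                                        "quadratic" = 0.1),
                       changePoint = 65, delta = log2(1.5), noiseSd = 0.5,
                       baselineMean = 8, baselineSd = 1,
                       detection = FALSE, fracUnexpressed = 0.1,
                       seed = 1L) {
    ageDist <- match.arg(ageDist)
    stopifnot(n >= 10, length(ageRange) == 2, ageRange[2] > ageRange[1],
              skew >= 0, nProbes >= 1, fracSignal >= 0, fracSignal <= 1,
              noiseSd >= 0)
    if (fracSignal > 0) {
        if (!all(names(archetypeMix) %in% setdiff(.ARCHETYPES, "null")))
            stop("unknown archetype in mixture: ",
                 paste(setdiff(names(archetypeMix),
                               .ARCHETYPES), collapse = ", "))
        if (abs(sum(archetypeMix) - 1) > 1e-8)
            stop("archetype mixture must sum to 1")
        if (changePoint < ageRange[1] || changePoint > ageRange[2])
            stop("change point must lie within the age range")
    }
    structure(list(n = as.integer(n), ageRange = as.numeric(ageRange),
                   ageDist = ageDist, skew = skew,
                   nProbes = as.integer(nProbes), fracSignal = fracSignal,
                   archetypeMix = archetypeMix, changePoint = changePoint,
                   delta = delta, noiseSd = noiseSd,
                   baselineMean = baselineMean, baselineSd = baselineSd,
                   detection = detection, fracUnexpressed = fracUnexpressed,
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

#' Cohort presets
#'
#' Two reference cohort designs. `rsLikeCohort()`: 762 samples aged 46-89,
#' positively skewed toward younger ages (elderly under-represented).
#' `shipLikeCohort()`: 991 samples aged 21-81 with a near-even age
#' distribution.
#'
#' @param ... overrides passed to [cohortSpec()].
#' @return A `CohortSpec`.
#' @export
rsLikeCohort <- function(...) {
    args <- list(n = 762, ageRange = c(46, 89), ageDist = "skewed", skew = 2)
    do.call(cohortSpec, utils::modifyList(args, list(...)))
}

#' @rdname rsLikeCohort
#' @export
shipLikeCohort <- function(...) {
    args <- list(n = 991, ageRange = c(21, 81), ageDist = "skewed",
                 skew = 0.3)
    do.call(cohortSpec, utils::modifyList(args, list(...)))
}

#' Draw sample ages for a cohort
#'
#' Uniform mode draws uniformly over the age range; skewed mode draws from
#' Beta(1, 1 + skew) rescaled to the range (positive sample skewness for
#' `skew > 0`, uniform at `skew = 0`).
#'
#' @param spec a `CohortSpec` (its `seed` is used unless `seed` is given).
#' @param seed optional override seed.
#' @return Numeric vector of `spec$n` ages within the range.
#' @export
sampleAges <- function(spec, seed = spec$seed) {
    withr::with_seed(as.integer(seed), {
        u <- if (spec$ageDist == "uniform" || spec$skew == 0)
            stats::runif(spec$n)
        else stats::rbeta(spec$n, 1, 1 + spec$skew)
    })
    spec$ageRange[1] + (spec$ageRange[2] - spec$ageRange[1]) * u
}

# Archetype mean trajectory at ages x. delta is the total log2 change over
# the range; hinges are flat at the baseline until the change point, then
# linear to baseline +/- delta at the range top; quadratics have their
# vertex at the change point and a total excursion of delta.
.archetypeMean <- function(archetype, x, lo, hi, cp, delta, baseline) {
    shape <- switch(archetype,
        "null" = rep(0, length(x)),
        "linear-up" = delta * (x - lo) / (hi - lo),
        "linear-down" = -delta * (x - lo) / (hi - lo),
        "hinge-up" = delta * pmax(0, x - cp) / (hi - cp),
        "hinge-down" = -delta * pmax(0, x - cp) / (hi - cp),
        "quadratic" = delta * (x - cp)^2 / max((hi - cp)^2, (lo - cp)^2),
        stop("unknown archetype: ", archetype))
    baseline + shape
}

# Largest-remainder apportionment of n items to the mixture fractions.
.apportion <- function(n, mix) {
    raw <- n * mix
    base <- floor(raw)
    left <- n - sum(base)
    if (left > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1
    }
    stats::setNames(as.integer(base), names(mix))
}

#' Simulate a cohort expression dataset with known truth
#'
#' The number of non-null probes is exactly
#' `round(nProbes * fracSignal)` (round-half-even, R's [round()]); they are
#' apportioned to the archetype mixture by largest remainder. Per-probe
#' baselines are Gaussian; noise is independent homoscedastic Gaussian on
#' the log2 scale. Fully reproducible from the spec seed.
#'
#' @param spec a [cohortSpec()].
#' @param probePrefix prefix for generated probe ids.
#' @return List with `dataset` (an [AgeExpressionSet-class]) and `truth`
#'   (a [S4Vectors::DataFrame] with `probe_id`, `archetype`, `change_point`,
#'   `delta`, `noise_sd`, `baseline`).
#' @export
simulateDataset <- function(spec, probePrefix = "p") {
    lo <- spec$ageRange[1]; hi <- spec$ageRange[2]
    agesDrawn <- sampleAges(spec)
    nSig <- round(spec$nProbes * spec$fracSignal)
    counts <- .apportion(nSig, spec$archetypeMix)
    archetypes <- c(rep("null", spec$nProbes - nSig),
                    rep(names(counts), counts))
    probeIds <- sprintf("%s%0*d", probePrefix,
                        nchar(spec$nProbes), seq_len(spec$nProbes))
    withr::with_seed(spec$seed + 1L, {
        baseline <- stats::rnorm(spec$nProbes, spec$baselineMean,
                                 spec$baselineSd)
        noise <- matrix(stats::rnorm(spec$nProbes * spec$n, 0, spec$noiseSd),
                        nrow = spec$nProbes)
        detection <- NULL
        unexpressed <- logical(spec$nProbes)
        if (spec$detection) {
            unexpressed <- seq_len(spec$nProbes) %in%
                sample.int(spec$nProbes,
                           round(spec$nProbes * spec$fracUnexpressed))
            # any non-null probe is by construction expressed
            unexpressed[archetypes != "null"] <- FALSE
            detection <- matrix(stats::runif(spec$nProbes * spec$n, 0, 0.01),
                                nrow = spec$nProbes)
            nu <- sum(unexpressed)
            if (nu > 0)
                detection[unexpressed, ] <- stats::runif(nu * spec$n)
        }
    })
    mu <- t(vapply(seq_len(spec$nProbes), function(i)
        .archetypeMean(archetypes[i], agesDrawn, lo, hi, spec$changePoint,
                       spec$delta, baseline[i]),
        numeric(spec$n)))
    values <- mu + noise
    dimnames(values) <- list(probeIds, sprintf("s%0*d", nchar(spec$n),
                                               seq_len(spec$n)))
    if (!is.null(detection)) dimnames(detection) <- dimnames(values)
    truth <- S4Vectors::DataFrame(
        probe_id = probeIds, archetype = archetypes,
        change_point = ifelse(archetypes %in%
                                  c("hinge-up", "hinge-down", "quadratic"),
                              spec$changePoint, NA_real_),
        delta = ifelse(archetypes == "null", 0, spec$delta),
        noise_sd = spec$noiseSd, baseline = baseline,
        unexpressed = unexpressed)
    list(dataset = AgeExpressionSet(values, ages = agesDrawn,
                                    detection = detection),
         truth = truth)
}

#' Simulate two cohorts measuring overlapping gene sets
#'
#' Emulates two array platforms profiling the same transcriptome: each
#' cohort's probes map onto a common gene namespace, a `sharedGeneFraction`
#' of the genes is measured by both platforms, and shared non-null genes
#' carry the same archetype and effect size in both cohorts, so overlap and
#' direction-concordance analyses have a known truth.
#'
#' @param specA,specB [cohortSpec()]s for the two cohorts (probe counts may
#'   differ; the shared genes are drawn from the smaller panel).
#' @param sharedGeneFraction fraction of the smaller panel's genes measured
#'   by both platforms.
#' @return List with `datasetA`, `datasetB`, `truthA`, `truthB`,
#'   `annotationA`, `annotationB` (probe -> gene DataFrames).
#' @export
simulatePlatformPair <- function(specA, specB, sharedGeneFraction = 0.9) {
    stopifnot(sharedGeneFraction >= 0, sharedGeneFraction <= 1)
    simA <- simulateDataset(specA, probePrefix = "A_p")
    nShared <- round(min(specA$nProbes, specB$nProbes) * sharedGeneFraction)
    # first nShared probes of A (in A's archetype layout) are the shared
    # genes; B measures them with its own probe ids and noise
    geneIds <- sprintf("g%05d", seq_len(specA$nProbes + specB$nProbes))
    genesA <- geneIds[seq_len(specA$nProbes)]
    genesB <- c(genesA[seq_len(nShared)],
                geneIds[specA$nProbes + seq_len(specB$nProbes - nShared)])
    truthA <- simA$truth
    # build B so that its first nShared probes inherit A's truth rows
    simB <- simulateDataset(specB, probePrefix = "B_p")
    truthB <- simB$truth
    shared <- seq_len(nShared)
    valB <- exprsValues(simB$dataset)
    agesB <- ages(simB$dataset)
    if (nShared > 0) {
        truthB$archetype[shared] <- truthA$archetype[shared]
        truthB$change_point[shared] <- truthA$change_point[shared]
        truthB$delta[shared] <- truthA$delta[shared]
        # regenerate B's expression for the shared probes under A's archetypes
        loB <- specB$ageRange[1]; hiB <- specB$ageRange[2]
        withr::with_seed(specB$seed + 2L, {
            noise <- matrix(stats::rnorm(nShared * specB$n, 0,
                                         specB$noiseSd),
                            nrow = nShared)
        })
        muShared <- t(vapply(shared, function(i)
            .archetypeMean(truthB$archetype[i], agesB, loB, hiB,
                           ifelse(is.na(truthB$change_point[i]),
                                  specB$changePoint,
                                  truthB$change_point[i]),
                           truthB$delta[i], truthB$baseline[i]),
            numeric(specB$n)))
        valB[shared, ] <- muShared + noise
    }
    datasetB <- AgeExpressionSet(valB, ages = agesB)
    annotationA <- S4Vectors::DataFrame(probe_id = rownames(simA$dataset),
                                        gene_id = genesA)
    annotationB <- S4Vectors::DataFrame(probe_id = rownames(datasetB),
                                        gene_id = genesB)
    list(datasetA = simA$dataset, datasetB = datasetB,
         truthA = truthA, truthB = truthB,
         annotationA = annotationA, annotationB = annotationB,
         sharedGenes = genesA[shared])
}
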