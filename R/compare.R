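#' @include AllClasses.R AllGenerics.R
NULL

# Cross-dataset and cross-condition comparisons.

#' Collapse significant probes to gene-level directions
#'
#' A gene's direction is the majority direction of its significant probes;
#' genes whose probes tie (equal numbers up and down) are excluded from the
#' map and reported separately. Unannotated probes are dropped.
#'
#' @param fits a [ProbeFitResults-class] restricted to significant probes.
#' @param annotation output of [joinAnnotation()] (or any table with
#'   `probe_id`, `gene_id`).
#' @return List with `directions` (named integer vector, gene -> +1/-1),
#'   `ties` (gene ids with internally discordant probes) and
#'   `unannotated` (probe ids without a gene).
#' @export
collapseToGenes <- function(fits, annotation) {
    tab <- fitTable(fits)
    gene <- as.character(annotation$gene_id)[
        match(tab$probe_id, as.character(annotation$probe_id))]
    unann <- tab$probe_id[is.na(gene)]
    ok <- !is.na(gene) & tab$direction != 0
    net <- tapply(tab$direction[ok], gene[ok], sum)
    ties <- names(net)[net == 0]
    net <- net[net != 0]
    dirs <- as.integer(sign(net))
    names(dirs) <- names(net)
    list(directions = dirs, ties = ties, unannotated = unann)
}

#' Overlap of two significant gene sets with direction concordance
#'
#' @param setA,setB named vectors mapping gene (or probe) id to direction
#'   (+1/-1).
#' @param reference which set supplies the percentage denominator
#'   (default `"A"`).
#' @return An [OverlapResult-class].
#' @export
overlapSignificant <- function(setA, setB, reference = c("A", "B")) {
    reference <- match.arg(reference)
    a <- as.integer(setA); names(a) <- names(setA)
    b <- as.integer(setB); names(b) <- names(setB)
    shared <- as.character(intersect(names(a), names(b)))
    conc <- as.character(shared[a[shared] == b[shared]])
    disc <- as.character(setdiff(shared, conc))
    refSize <- if (reference == "A") length(a) else length(b)
    pct <- if (refSize == 0) NA_real_ else 100 * length(shared) / refSize
    methods::new("OverlapResult", setA = a, setB = b, shared = shared,
                 concordant = conc, discordant = disc,
                 reference = reference, overlapPercent = pct)
}

setMethod("show", "OverlapResult", function(object) {
    cat("OverlapResult:", length(object@setA), "vs", length(object@setB),
        "significant ids\n")
    pct <- if (is.na(object@overlapPercent)) "undefined (empty reference)"
           else sprintf("%.1f%% of set %s", object@overlapPercent,
                        object@reference)
    cat(sprintf("  overlap %d (%s); concordant %d, discordant %d\n",
                length(object@shared), pct, length(object@concordant),
                length(object@discordant)))
    invisible(NULL)
})

#' Compare weighted and unweighted significant sets
#'
#' Runs the fit + filter stages twice on the same dataset - once with
#' moving-window weights, once without - and reports the overlap of the two
#' significant sets with the non-weighted set as reference. Probe-level by
#' default; gene-level when an annotation is supplied.
#'
#' @param dataset an [AgeExpressionSet-class].
#' @param config an [AnalysisConfig-class].
#' @param annotation optional probe-to-gene table for gene-level overlap.
#' @return List with `overlap` (an [OverlapResult-class], reference =
#'   unweighted), `weightedOnly` and `unweightedOnly` id vectors, and the
#'   two filter summaries.
#' @export
compareWeightingModes <- function(dataset, config = analysisConfig(),
                                  annotation = NULL) {
    w <- cohortWeights(dataset, config@windowHalfwidth)
    runs <- list(
        weighted = filterProbes(fitProbes(dataset, w, config),
                                config@fdrThreshold, config@absFcThreshold),
        unweighted = filterProbes(fitProbes(dataset, NULL, config),
                                  config@fdrThreshold, config@absFcThreshold))
    toMap <- function(run) {
        tab <- fitTable(run$fits)
        if (is.null(annotation)) {
            d <- as.integer(tab$direction)
            names(d) <- tab$probe_id
            d[d != 0]
        } else collapseToGenes(run$fits, annotation)$directions
    }
    mw <- toMap(runs$weighted)
    mu <- toMap(runs$unweighted)
    ov <- overlapSignificant(mu, mw, reference = "A")
    list(overlap = ov,
         weightedOnly = setdiff(names(mw), names(mu)),
         unweightedOnly = setdiff(names(mu), names(mw)),
         weightedSummary = runs$weighted$summary,
         unweightedSummary = runs$unweighted$summary)
}

#' Restrict two cohorts to their common age range
#'
#' Both datasets are restricted to samples whose age lies in
#' `[max(minA, minB), min(maxA, maxB)]`, bounds inclusive.
#'
#' @param datasetA,datasetB [AgeExpressionSet-class] objects.
#' @return List with `datasetA`, `datasetB` and `range` (the common bounds).
#' @export
matchAgeRange <- function(datasetA, datasetB) {
    lo <- max(min(ages(datasetA)), min(ages(datasetB)))
    hi <- min(max(ages(datasetA)), max(ages(datasetB)))
    if (lo > hi)
        stop("age ranges are disjoint: no common range to match")
    list(datasetA = datasetA[, ages(datasetA) >= lo & ages(datasetA) <= hi],
         datasetB = datasetB[, ages(datasetB) >= lo & ages(datasetB) <= hi],
         range = c(lo, hi))
}

#' Split a cohort at an age cut-off
#'
#' Younger subset: `age < cutoff`; older subset: `age >= cutoff`. The two
#' subsets partition the cohort exactly; each is intended to re-enter the
#' full pipeline independently (weights are recomputed within a subset).
#'
#' @param dataset an [AgeExpressionSet-class].
#' @param cutoff age in years, inside the observed range.
#' @return List with `younger` and `older` datasets.
#' @export
splitByAge <- function(dataset, cutoff) {
    a <- ages(dataset)
    if (cutoff <= min(a) || cutoff > max(a))
        stop("cutoff ", cutoff, " lies outside the observed age range")
    younger <- dataset[, a < cutoff]
    older <- dataset[, a >= cutoff]
    for (nm in c("younger", "older")) {
        n <- ncol(get(nm))
        if (n < 5L)
            stop(nm, " subset has only ", n,
                 " samples; the quadratic fit is unidentifiable")
        if (n < 10L)
            warning(nm, " subset has only ", n, " samples")
    }
    list(younger = younger, older = older)
}

#' Export ranked gene lists for external enrichment tools
#'
#' Writes three plain-text lists (`all`, `up`, `down`) of gene ids ordered
#' by ascending q-value, one id per line. Unannotated probes are excluded;
#' a gene's q-value is the best q among its probes.
#'
#' @param fits a [ProbeFitResults-class] restricted to significant probes.
#' @param annotation probe-to-gene table.
#' @param prefix output path prefix; files are `<prefix>_all.txt`,
#'   `<prefix>_up.txt`, `<prefix>_down.txt`.
#' @return Named character vector of the written paths, invisibly.
#' @export
exportGeneLists <- function(fits, annotation, prefix) {
    tab <- fitTable(fits)
    gene <- as.character(annotation$gene_id)[
        match(tab$probe_id, as.character(annotation$probe_id))]
    keep <- !is.na(gene)
    df <- data.frame(gene = gene[keep], q = tab$qvalue[keep],
                     dir = tab$direction[keep], stringsAsFactors = FALSE)
    collapse <- function(d) {
        if (nrow(d) == 0L) return(character(0))
        best <- tapply(d$q, d$gene, min)
        names(sort(best))
    }
    dirs <- collapseToGenes(fits, annotation)$directions
    paths <- c(all = paste0(prefix, "_all.txt"),
               up = paste0(prefix, "_up.txt"),
               down = paste0(prefix, "_down.txt"))
    writeLines(collapse(df), paths["all"])
    writeLines(collapse(df[df$gene %in% names(dirs)[dirs > 0], , drop = FALSE]),
               paths["up"])
    writeLines(collapse(df[df$gene %in% names(dirs)[dirs < 0], , drop = FALSE]),
               paths["down"])
    invisible(paths)
}
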