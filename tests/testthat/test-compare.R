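test_that("overlap arithmetic and direction concordance follow set rules", {
    A <- c(g1 = 1L, g2 = 1L, g3 = -1L)
    B <- c(g2 = 1L, g3 = 1L, g4 = -1L)
    ov <- overlapSignificant(A, B)
    expect_setequal(ov@shared, c("g2", "g3"))
    expect_identical(ov@concordant, "g2")
    expect_identical(ov@discordant, "g3")
    expect_equal(ov@overlapPercent, 100 * 2 / 3)
    # identical maps: full overlap and concordance
    same <- overlapSignificant(A, A)
    expect_equal(same@overlapPercent, 100)
    expect_equal(length(same@concordant), 3)
    expect_equal(length(same@discordant), 0)
    # disjoint maps
    expect_equal(length(overlapSignificant(A, c(g9 = 1L))@shared), 0)
    # empty reference -> undefined percentage
    expect_true(is.na(overlapSignificant(integer(0), B)@overlapPercent))
    # swapping A and B changes only the denominator
    ba <- overlapSignificant(B, A)
    expect_setequal(ba@shared, ov@shared)
    expect_setequal(ba@concordant, ov@concordant)
})

test_that("probes collapse to genes by majority direction with ties excluded", {
    tab <- S4Vectors::DataFrame(
        probe_id = paste0("p", 1:6),
        alpha = 0, beta = 0, gamma = 0, pvalue = 0.001,
        qvalue = c(0.01, 0.01, 0.01, 0.01, 0.02, 0.03),
        fold_change = c(1.5, 1.5, -1.5, 1.5, -1.5, 1.4),
        direction = c(1L, 1L, -1L, 1L, -1L, 1L), perfect_fit = FALSE)
    fits <- new("ProbeFitResults", table = tab, smoothed = matrix(0, 6, 2),
                ageGrid = c(1, 2), fcMode = "endpoints", weighted = FALSE)
    ann <- S4Vectors::DataFrame(
        probe_id = paste0("p", 1:5),
        gene_id = c("gA", "gA", "gA", "gB", "gB"))
    out <- collapseToGenes(fits, ann)
    expect_identical(out$directions, c(gA = 1L))   # gA: 2 up vs 1 down
    expect_identical(out$ties, "gB")               # gB: 1 up vs 1 down
    expect_identical(out$unannotated, "p6")
})

test_that("age-range matching trims both cohorts to the inclusive common range", {
    set.seed(31)
    dsA <- makeTinyDataset(matrix(rnorm(5 * 40, 8), 5, 40),
                           ages = c(46, 81, runif(37, 46, 89), 89))
    dsB <- makeTinyDataset(matrix(rnorm(5 * 50, 8), 5, 50),
                           ages = c(21, 46, 81, runif(47, 21, 81)))
    m <- matchAgeRange(dsA, dsB)
    expect_equal(m$range, c(46, 81))
    expect_true(all(ages(m$datasetA) >= 46 & ages(m$datasetA) <= 81))
    expect_true(all(ages(m$datasetB) >= 46 & ages(m$datasetB) <= 81))
    # bounds are retained
    expect_true(any(ages(m$datasetA) == 46) && any(ages(m$datasetA) == 81))
    # idempotent
    m2 <- matchAgeRange(m$datasetA, m$datasetB)
    expect_identical(colnames(m2$datasetA), colnames(m$datasetA))
    expect_identical(colnames(m2$datasetB), colnames(m$datasetB))
    # identical ranges leave both unchanged
    m3 <- matchAgeRange(dsB, dsB)
    expect_identical(colnames(m3$datasetA), colnames(dsB))
    # disjoint ranges are an error
    young <- makeTinyDataset(matrix(rnorm(5 * 12, 8), 5, 12),
                             ages = runif(12, 20, 30))
    old <- makeTinyDataset(matrix(rnorm(5 * 12, 8), 5, 12),
                           ages = runif(12, 60, 70))
    expect_error(matchAgeRange(young, old), "disjoint")
})

test_that("the age split partitions the cohort at the >= boundary", {
    young <- c(seq(60, 64, by = 0.5), 64.9)
    old <- c(65, seq(65.5, 70, by = 0.5))
    ds <- makeTinyDataset(matrix(rnorm(4 * 21, 8), 4, 21),
                          ages = c(young, old))
    sp <- splitByAge(ds, 65)
    expect_equal(sort(ages(sp$younger)), young)
    expect_equal(sort(ages(sp$older)), old)
    # partition: union of the two subsets is the cohort, disjoint
    expect_setequal(c(colnames(sp$younger), colnames(sp$older)),
                    colnames(ds))
    expect_length(intersect(colnames(sp$younger), colnames(sp$older)), 0)
    expect_error(splitByAge(ds, 10), "outside")
    expect_error(splitByAge(ds, 62), "unidentifiable")
})

test_that("weighting-mode comparison reduces to identity when weights are equal", {
    set.seed(41)
    # all ages within one window: every weight equal, weighted == unweighted
    ds <- makeTinyDataset(matrix(rnorm(30 * 40, 8), 30, 40),
                          ages = runif(40, 60, 65))
    cw <- compareWeightingModes(ds)
    expect_true(all(sampleWeights(cohortWeights(ds)) == 1 / 40))
    expect_equal(cw$overlap@overlapPercent,
                 if (length(cw$overlap@setA)) 100 else NA_real_)
    expect_length(cw$weightedOnly, 0)
    expect_length(cw$unweightedOnly, 0)
    expect_identical(cw$weightedSummary$nFDRFC, cw$unweightedSummary$nFDRFC)
})

test_that("weighting recovers at least as many late-change probes in a skewed cohort", {
    spec <- rsLikeCohort(n = 400, nProbes = 400, fracSignal = 0.3,
                         archetypeMix = c("hinge-up" = 0.5,
                                          "hinge-down" = 0.5),
                         changePoint = 75, delta = 0.8, seed = 19)
    sim <- simulateDataset(spec)
    cw <- compareWeightingModes(sim$dataset)
    planted <- sim$truth$probe_id[sim$truth$archetype != "null"]
    recovered <- function(ids) length(intersect(ids, planted))
    wIds <- names(cw$overlap@setB)
    uIds <- names(cw$overlap@setA)
    expect_gte(recovered(wIds), recovered(uIds))
})

test_that("gene lists export ranked by q-value, split by direction", {
    tab <- S4Vectors::DataFrame(
        probe_id = paste0("p", 1:4),
        alpha = 0, beta = 0, gamma = 0, pvalue = 1e-4,
        qvalue = c(0.03, 0.001, 0.02, 0.04),
        fold_change = c(1.5, 1.6, -1.5, 1.3),
        direction = c(1L, 1L, -1L, 1L), perfect_fit = FALSE)
    fits <- new("ProbeFitResults", table = tab, smoothed = matrix(0, 4, 2),
                ageGrid = c(1, 2), fcMode = "endpoints", weighted = FALSE)
    ann <- S4Vectors::DataFrame(probe_id = paste0("p", 1:3),
                                gene_id = c("gA", "gB", "gC"))
    dir <- withr::local_tempdir()
    paths <- exportGeneLists(fits, ann, file.path(dir, "lists"))
    expect_identical(readLines(paths[["all"]]), c("gB", "gC", "gA"))
    expect_identical(readLines(paths[["up"]]), c("gB", "gA"))
    expect_identical(readLines(paths[["down"]]), "gC")
    # p4 was unannotated: absent everywhere
    expect_false(any(grepl("p4", unlist(lapply(paths, readLines)))))
    # no significant genes -> three empty files
    none <- filterProbes(fits, 1e-9, 10)$fits
    paths2 <- exportGeneLists(none, ann, file.path(dir, "none"))
    expect_true(all(vapply(paths2, function(p) length(readLines(p)) == 0,
                           TRUE)))
})
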