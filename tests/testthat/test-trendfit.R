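test_that("noiseless quadratic signals are recovered exactly", {
    x <- seq(40, 80, length.out = 30)
    y <- 2 + 0.1 * x + 0.01 * x^2
    for (w in list(NULL, runif(30, 0.1, 2))) {
        fit <- fitQuadratic(y, x, w)
        expect_equal(fit$alpha, 2, tolerance = 1e-8)
        expect_equal(fit$beta, 0.1, tolerance = 1e-8)
        expect_equal(fit$gamma, 0.01, tolerance = 1e-8)
    }
    flat <- fitQuadratic(rep(3.5, 10), seq(40, 80, length.out = 10))
    expect_equal(flat$alpha, 3.5, tolerance = 1e-10)
    expect_equal(flat$beta, 0, tolerance = 1e-10)
    expect_equal(flat$gamma, 0, tolerance = 1e-10)
    expect_error(fitQuadratic(1:4, c(50, 50, 60, 60)), "distinct ages")
    expect_error(fitQuadratic(c(1, NA, 3, 4, 5), c(41:45)), "finite")
})

test_that("weighted fits match the lm(weights=) oracle on random instances", {
    set.seed(101)
    for (i in 1:50) {
        n <- sample(5:50, 1)
        x <- runif(n, 20, 90)
        y <- rnorm(n, 5, 2)
        w <- runif(n, 0.05, 3)
        fit <- fitQuadratic(y, x, w)
        orc <- unname(coef(lm(y ~ x + I(x^2), weights = w)))
        expect_equal(c(fit$alpha, fit$beta, fit$gamma), orc,
                     tolerance = 1e-8)
    }
    # the spec's 4-point, weight-10 example against explicit normal equations
    x <- c(40, 50, 60, 70); y <- c(1, 3, 2, 5); w <- c(1, 1, 1, 10)
    X <- cbind(1, x, x^2)
    orc <- drop(solve(t(X * w) %*% X, t(X * w) %*% y))
    fit <- fitQuadratic(y, x, w)
    expect_equal(c(fit$alpha, fit$beta, fit$gamma), unname(orc),
                 tolerance = 1e-8)
})

test_that("fit statistics are invariant to a global weight rescaling", {
    set.seed(5)
    n <- 60
    x <- runif(n, 46, 89)
    ds <- makeTinyDataset(matrix(rnorm(5 * n, 8), 5, n), ages = x)
    w <- runif(n, 0.1, 1)
    a <- fitProbes(ds, w)
    b <- fitProbes(ds, w * 817.3)
    expect_equal(fitTable(a)$alpha, fitTable(b)$alpha, tolerance = 1e-12)
    expect_equal(fitTable(a)$pvalue, fitTable(b)$pvalue, tolerance = 1e-12)
    expect_equal(fitTable(a)$fold_change, fitTable(b)$fold_change,
                 tolerance = 1e-12)
})

test_that("smoothed trajectories are exact quadratics on the grid", {
    expect_equal(smoothTrajectory(list(alpha = 0, beta = 0, gamma = 1), 3), 9)
    expect_equal(smoothTrajectory(list(alpha = 2, beta = 0.1, gamma = 0.01),
                                  50), 32)
    aff <- smoothTrajectory(list(alpha = 1, beta = 2, gamma = 0), 40:50)
    expect_equal(unique(diff(diff(aff))), 0)
    # from a fitted cohort: constant second differences on the unit grid
    spec <- cohortSpec(n = 80, nProbes = 5, fracSignal = 1, seed = 8)
    fits <- fitProbes(simulateDataset(spec)$dataset)
    sm <- smoothedTrajectories(fits)
    d2 <- t(apply(sm, 1, function(r) diff(diff(r))))
    expect_lt(max(abs(d2 - d2[, 1])), 1e-8)
})

test_that("the F-test behaves at its limits and is uniform under the null", {
    x <- seq(40, 80, length.out = 20)
    # perfect quadratic fit -> essentially zero p, flagged at exact zero RSS
    p <- ageAssociationTest(2 + 0.05 * x + 0.002 * x^2, x)
    expect_lt(p, 1e-12)
    # constant y -> F = 0, p = 1
    expect_equal(as.numeric(ageAssociationTest(rep(2, 20), x)), 1)
    # matches anova() on a weighted instance
    set.seed(12)
    y <- rnorm(20); w <- runif(20, 0.2, 2)
    f1 <- lm(y ~ x + I(x^2), weights = w)
    f0 <- lm(y ~ 1, weights = w)
    expect_equal(as.numeric(ageAssociationTest(y, x, w)),
                 anova(f0, f1)$`Pr(>F)`[2], tolerance = 1e-10)
    # unweighted null p-values are uniform (KS on 2000 probes, n = 200)
    set.seed(77)
    n <- 200
    ages <- runif(n, 46, 89)
    ds <- AgeExpressionSet(matrix(rnorm(2000 * n), 2000, n,
                                  dimnames = list(paste0("p", 1:2000),
                                                  paste0("s", 1:n))),
                           ages = ages)
    pv <- fitTable(fitProbes(ds))$pvalue
    ks <- suppressWarnings(ks.test(pv, "punif"))
    expect_lt(unname(ks$statistic), 0.03)
})

test_that("BH adjustment matches brute force and p.adjust, and is monotone", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(c(0.005, 0.04)), c(0.01, 0.04))
    expect_equal(bhAdjust(0.3), 0.3)
    expect_identical(bhAdjust(numeric(0)), numeric(0))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(42)
    for (i in 1:30) {
        p <- runif(sample(1:400, 1))
        q <- bhAdjust(p)
        expect_equal(q, bruteForceBH(p))
        expect_equal(q, p.adjust(p, "BH"))
        expect_true(all(q >= p))
        o <- order(p)
        expect_true(all(diff(q[o]) >= -1e-15))
    }
})

test_that("fold change follows the 2^delta convention with endpoint direction", {
    fc <- foldChange(c(7.000, 7.1, 7.263))
    expect_equal(fc$fold_change, 2^0.263, tolerance = 1e-12)
    expect_equal(fc$direction, 1)
    flat <- foldChange(rep(5, 10))
    expect_equal(flat$fold_change, 1)
    expect_equal(flat$direction, 0)
    down <- foldChange(c(8, 7.5, 7))
    expect_equal(down$fold_change, -2)
    expect_equal(down$direction, -1)
    # amplitude mode: symmetric excursion with small endpoint change
    tr <- 5 + c(0, 1, 0.05)
    amp <- foldChange(tr, mode = "amplitude")
    expect_equal(amp$fold_change, 2^1, tolerance = 1e-12)
    expect_equal(amp$direction, 1)
    expect_equal(amp$mode, "amplitude")
})

test_that("the joint FDR + fold-change filter applies both rules and keeps the boundary", {
    tab <- S4Vectors::DataFrame(
        probe_id = paste0("p", 1:4),
        alpha = 0, beta = 0, gamma = 0,
        pvalue = c(0.001, 0.001, 0.1, 0.01),
        qvalue = c(0.01, 0.01, 0.2, 0.04),
        fold_change = c(1.5, 1.1, 2.0, -1.2),
        direction = c(1L, 1L, 1L, -1L), perfect_fit = FALSE)
    fits <- new("ProbeFitResults", table = tab,
                smoothed = matrix(0, 4, 3), ageGrid = c(1, 2, 3),
                fcMode = "endpoints", weighted = FALSE)
    out <- filterProbes(fits)
    expect_identical(fitTable(out$fits)$probe_id, c("p1", "p4"))
    expect_equal(out$summary$nFDRFC, 2)
    expect_equal(out$summary$nFDR, 3)
    expect_identical(out$category, c("fdr_fc", "fdr", "ns", "fdr_fc"))
    # permissive thresholds keep everything
    expect_equal(filterProbes(fits, 1 - 1e-12, 1)$summary$nFDRFC, 4)
    # empty input stays empty
    expect_equal(filterProbes(out$fits, 1e-9, 10)$summary$nFDRFC, 0)
    dirs <- tabulateDirections(out$fits)
    expect_equal(dirs, list(positive = 1L, negative = 1L, zero = 0L,
                            total = 2L))
})

test_that("null cohorts rarely yield BH discoveries and the FDP stays controlled", {
    set.seed(60)
    reps <- 10
    fdp <- numeric(reps)
    for (r in seq_len(reps)) {
        n <- 150
        ds <- AgeExpressionSet(matrix(rnorm(800 * n), 800, n,
                                      dimnames = list(paste0("p", 1:800),
                                                      paste0("s", 1:n))),
                               ages = runif(n, 46, 89))
        q <- fitTable(fitProbes(ds))$qvalue
        calls <- sum(q < 0.05)
        fdp[r] <- if (calls > 0) 1 else 0   # every call is false here
    }
    mcse <- sd(fdp) / sqrt(reps)
    expect_lte(mean(fdp), 0.05 + 3 * mcse + 1e-12)
})

test_that("planted log2(1.5) trends are recovered by the joint filter with unbiased effect sizes", {
    spec <- cohortSpec(n = 500, nProbes = 600, fracSignal = 0.5,
                       ageDist = "uniform",
                       archetypeMix = c("linear-up" = 0.5,
                                        "linear-down" = 0.5),
                       delta = log2(1.5), noiseSd = 0.5, seed = 14)
    sim <- simulateDataset(spec)
    w <- cohortWeights(sim$dataset)
    fl <- filterProbes(fitProbes(sim$dataset, w))
    truth <- sim$truth
    planted <- truth$probe_id[truth$archetype != "null"]
    recovered <- intersect(fitTable(fl$fits)$probe_id, planted)
    expect_gte(length(recovered) / length(planted), 0.9)
    # estimated total change over the planted age range (46-89) is
    # unbiased; evaluated from the coefficients because the observed ages
    # of a skewed cohort need not reach the range top
    fits <- fitProbes(sim$dataset, w)
    tabf <- fitTable(fits)
    est <- tabf$beta * (89 - 46) + tabf$gamma * (89^2 - 46^2)
    names(est) <- tabf$probe_id
    sgn <- ifelse(truth$archetype == "linear-down", -1, 1)
    err <- (est[planted] * sgn[truth$archetype != "null"]) - log2(1.5)
    se <- sd(err) / sqrt(length(err))
    expect_lt(abs(mean(err)), 3 * se)
})
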