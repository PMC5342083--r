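test_that("standardization centres trajectories and is idempotent", {
    expect_equal(unname(standardizeTrajectories(rbind(c(1, 2, 3)))),
                 rbind(c(-1, 0, 1)))
    expect_equal(unname(standardizeTrajectories(rbind(rep(4, 5)))),
                 rbind(rep(0, 5)))
    set.seed(2)
    m <- matrix(rnorm(50), 5, 10)
    s <- standardizeTrajectories(m)
    expect_equal(standardizeTrajectories(s), s)
    expect_lt(max(abs(rowMeans(s))), 1e-12)
})

test_that("absolute-correlation distance treats mirrored trends as identical", {
    grid <- 40:80
    t1 <- sin(grid / 10)
    d <- ageTrends:::.absCorDist(rbind(t1, -t1, t1), rbind(t1))
    expect_equal(unname(d[, 1]), c(0, 0, 0), tolerance = 1e-12)
    set.seed(3)
    m <- matrix(rnorm(60), 6, 10)
    D <- ageTrends:::.absCorDist(m, m)
    expect_true(all(D >= -1e-12 & D <= 1 + 1e-12))
    expect_lt(max(abs(diag(D))), 1e-12)
})

test_that("K-means separates planted opposite shapes and unites mirrors under abscor", {
    set.seed(17)
    grid <- 46:89
    traj <- makeHingeTrajectories(grid, cp = 65, nUp = 20, nDown = 20,
                                  jitter = 0.02)
    cl <- kmeansTrends(traj, k = 2, metric = "euclidean", seed = 1)
    a <- clusterAssignments(cl)
    expect_equal(length(unique(a[1:20])), 1)
    expect_equal(length(unique(a[21:40])), 1)
    expect_false(a[1] == a[21])
    # under absolute correlation, mirrored families unite and distinct
    # shapes separate: hinges (up+down) vs straight lines (up+down)
    line <- grid - mean(grid)
    mixed <- rbind(traj[c(1:5, 21:25), ],
                   l1 = line, l2 = -line, l3 = line, l4 = -line)
    a2 <- clusterAssignments(kmeansTrends(mixed, k = 2, metric = "abscor",
                                          seed = 1))
    expect_equal(length(unique(a2[1:10])), 1)      # all hinges together
    expect_equal(length(unique(a2[11:14])), 1)     # all lines together
    expect_false(a2[[1]] == a2[[11]])
    # k = 1 puts everything together
    one <- kmeansTrends(traj, k = 1, metric = "euclidean", seed = 1)
    expect_true(all(clusterAssignments(one) == 1L))
    expect_error(kmeansTrends(traj, k = 100, seed = 1), "exceeds")
    flat <- rbind(traj, t0 = rep(0, length(grid)))
    expect_error(kmeansTrends(flat, k = 2, metric = "abscor", seed = 1),
                 "t0")
})

test_that("clustering is deterministic given the seed and sign-invariant under abscor", {
    set.seed(23)
    grid <- 40:80
    traj <- makeHingeTrajectories(grid, cp = 60, nUp = 15, nDown = 15,
                                  jitter = 0.05)
    c1 <- kmeansTrends(traj, k = 4, metric = "abscor", seed = 9)
    c2 <- kmeansTrends(traj, k = 4, metric = "abscor", seed = 9)
    expect_identical(clusterAssignments(c1), clusterAssignments(c2))
    # flipping a subset of trajectories leaves the partition unchanged
    flip <- traj
    flip[c(2, 5, 18), ] <- -flip[c(2, 5, 18), ]
    c3 <- kmeansTrends(flip, k = 4, metric = "abscor", seed = 9)
    samePartition <- function(a, b) {
        all(outer(a, a, "==") == outer(b, b, "=="))
    }
    expect_true(samePartition(clusterAssignments(c1),
                              clusterAssignments(c3)))
})

test_that("redundant clusters merge on signed correlation and singletons are dropped", {
    grid <- 1:10
    base <- rbind(a1 = grid, a2 = grid + 0.01, a3 = grid - 0.01,
                  b1 = -1.0 * grid, b2 = -1.0 * grid + 0.02,
                  lone = c(rep(0, 9), 5))
    base <- standardizeTrajectories(base)
    cl <- kmeansTrends(base, k = 4, metric = "euclidean", seed = 2)
    merged <- mergeRedundantClusters(cl, corrThreshold = 0.9)
    # rising family and falling family survive; the singleton is gone
    expect_equal(length(clusterSizes(merged)), 2)
    a <- clusterAssignments(merged)
    expect_true(is.na(a[["lone"]]))
    expect_equal(length(unique(a[c("a1", "a2", "a3")])), 1)
    expect_equal(length(unique(a[c("b1", "b2")])), 1)
    # opposite trends (r = -1) are never merged
    expect_false(a[["a1"]] == a[["b1"]])
    lab <- labelInclinations(merged)
    inc <- inclinations(lab)
    expect_setequal(inc, c("positive", "negative"))
    expect_equal(inc[a[["a1"]]], "positive")
    expect_equal(inc[a[["b1"]]], "negative")
})

test_that("two centred lines of opposite slope cross at the grid midpoint", {
    grid <- 40:80
    up <- grid - mean(grid)
    traj <- rbind(u1 = up, u2 = up, d1 = -up, d2 = -up)
    ap <- detectAgePosition(traj, ageGrid = grid, k = 2, seed = 1)
    expect_equal(positionAge(ap), 60)
    expect_equal(positionDecade(ap), 7L)
    expect_equal(ap@method, "trajectory-crossing")
})

test_that("the crossing of centred hinges sits where the ramp passes its mean", {
    # analytic oracle: centred flat-then-ramp equals its mirror where
    # ramp(x) = mean(ramp); for cp = 65 on 46..89 that is 65 + 24 * mean
    grid <- 46:89
    cp <- 65
    ramp <- pmax(0, grid - cp) / (max(grid) - cp)
    crossing <- cp + (max(grid) - cp) * mean(ramp)
    traj <- makeHingeTrajectories(grid, cp = cp, nUp = 10, nDown = 10)
    ap <- detectAgePosition(traj, ageGrid = grid, k = 2, seed = 1)
    expect_equal(positionAge(ap), crossing, tolerance = 1e-8)
})

test_that("age-position detection is translation-equivariant and handles degenerate input", {
    grid <- 46:89
    traj <- makeHingeTrajectories(grid, cp = 65, nUp = 8, nDown = 8)
    ap0 <- detectAgePosition(traj, ageGrid = grid, k = 2, seed = 1)
    shift <- 12.5
    ap1 <- detectAgePosition(traj, ageGrid = grid + shift, k = 2, seed = 1)
    expect_equal(positionAge(ap1), positionAge(ap0) + shift,
                 tolerance = 1e-8)
    # single-inclination input reports absence rather than erroring
    up <- makeHingeTrajectories(grid, cp = 65, nUp = 6, nDown = 0)
    apNone <- detectAgePosition(up, ageGrid = grid, k = 2, seed = 1)
    expect_true(is.na(positionAge(apNone)))
    expect_match(apNone@note, "single-signed|never cross")
})

test_that("the quadratic-vertex alternative reports its method and a quadratic's vertex", {
    grid <- 40:90
    q <- (grid - 63)^2 / 100
    traj <- standardizeTrajectories(rbind(q1 = q, q2 = q, m1 = -q, m2 = -q))
    ap <- detectAgePosition(traj, ageGrid = grid, k = 2, seed = 1,
                            method = "quadratic-vertex")
    expect_equal(ap@method, "quadratic-vertex")
    expect_equal(positionAge(ap), 63, tolerance = 1e-6)
})
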