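#' @include AllClasses.R AllGenerics.R
NULL

# K-means over standardized trajectories under two metrics, cluster
# merging, inclination labelling, and age-position extraction.

#' Standardize smoothed trajectories
#'
#' Subtracts each trajectory's mean over the age grid, so probes group by
#' trend shape rather than absolute intensity. Idempotent.
#'
#' @param trajectories probe-by-grid matrix (or a [ProbeFitResults-class],
#'   whose smoothed trajectories are used).
#' @return Row-centred matrix of the same shape.
#' @export
standardizeTrajectories <- function(trajectories) {
    if (methods::is(trajectories, "ProbeFitResults"))
        trajectories <- smoothedTrajectories(trajectories)
    trajectories <- as.matrix(trajectories)
    trajectories - rowMeans(trajectories)
}

# Absolute-correlation distance matrix between rows of A and rows of B:
# d = 1 - |pearson|. Rows must be non-constant.
.absCorDist <- function(A, B) {
    1 - abs(stats::cor(t(A), t(B)))
}

.sqEuclidDist <- function(A, B) {
    an <- rowSums(A^2)
    bn <- rowSums(B^2)
    outer(an, bn, "+") - 2 * tcrossprod(A, B)
}

.clusterDist <- function(A, B, metric) {
    if (metric == "euclidean") .sqEuclidDist(A, B) else .absCorDist(A, B)
}

# Farthest-point seeding: random first centre, then repeatedly the point
# farthest (max min-distance) from the chosen centres. Deterministic given
# the first index.
.farthestPointSeed <- function(traj, k, firstIdx, metric) {
    centres <- integer(k)
    centres[1] <- firstIdx
    if (k > 1L) {
        dmin <- .clusterDist(traj, traj[firstIdx, , drop = FALSE], metric)[, 1]
        for (i in 2:k) {
            centres[i] <- which.max(dmin)
            dnew <- .clusterDist(traj,
                                 traj[centres[i], , drop = FALSE], metric)[, 1]
            dmin <- pmin(dmin, dnew)
        }
    }
    centres
}

# One Lloyd run from given initial centroids; returns assignment, centroids
# and the total within-cluster distance.
.lloyd <- function(traj, centroids, metric, maxIter = 100L) {
    n <- nrow(traj)
    k <- nrow(centroids)
    assign <- integer(n)
    for (iter in seq_len(maxIter)) {
        D <- .clusterDist(traj, centroids, metric)
        newAssign <- max.col(-D, ties.method = "first")
        # re-seed empty clusters with the worst-fitted point
        for (j in seq_len(k)) {
            if (!any(newAssign == j)) {
                far <- which.max(D[cbind(seq_len(n), newAssign)])
                newAssign[far] <- j
                D[far, ] <- Inf
            }
        }
        if (identical(newAssign, assign)) break
        assign <- newAssign
        for (j in seq_len(k)) {
            members <- traj[assign == j, , drop = FALSE]
            if (metric == "abscor") {
                # flip members negatively correlated with the current centroid
                cc <- stats::cor(t(members), centroids[j, ])
                members <- members * ifelse(drop(cc) < 0, -1, 1)
            }
            centroids[j, ] <- colMeans(members)
        }
    }
    D <- .clusterDist(traj, centroids, metric)
    total <- sum(D[cbind(seq_len(n), assign)])
    list(assignment = assign, centroids = centroids, total = total)
}

#' K-means clustering of expression trajectories
#'
#' Lloyd-style K-means with farthest-point seeding, under either squared
#' Euclidean distance (trend grouping) or absolute-correlation distance
#' `d(a, b) = 1 - |pearson(a, b)|` (which unites a trend with its mirror
#' image and exposes the conjunction point). Under the correlation metric a
#' centroid is the mean of its members after flipping the sign of members
#' negatively correlated with the current centroid. `restarts` independent
#' seedings are run and the partition with the smallest total within-cluster
#' distance wins; the whole procedure is deterministic given `seed`.
#'
#' @param trajectories probe-by-grid matrix of standardized trajectories.
#' @param k number of clusters.
#' @param metric `"euclidean"` or `"abscor"`.
#' @param seed integer seed for the restarts' initial centres.
#' @param ageGrid the grid the trajectories live on (recorded; defaults to
#'   column names).
#' @param restarts number of seedings (default 5).
#' @param maxIter Lloyd iteration cap.
#' @return A [TrendClusterSet-class].
#' @export
kmeansTrends <- function(trajectories, k, metric = c("euclidean", "abscor"),
                         seed = 1L, ageGrid = NULL, restarts = 5L,
                         maxIter = 100L) {
    metric <- match.arg(metric)
    traj <- as.matrix(trajectories)
    n <- nrow(traj)
    if (k > n)
        stop("k (", k, ") exceeds the number of trajectories (", n, ")")
    if (metric == "abscor") {
        sds <- apply(traj, 1, stats::sd)
        if (any(sds == 0))
            stop("constant trajectory under the correlation metric: ",
                 paste(utils::head(rownames(traj)[sds == 0], 3),
                       collapse = ", "))
    }
    if (is.null(ageGrid)) {
        ageGrid <- suppressWarnings(as.numeric(colnames(traj)))
        if (anyNA(ageGrid)) ageGrid <- seq_len(ncol(traj))
    }
    best <- NULL
    withr::with_seed(as.integer(seed), {
        firsts <- sample.int(n, restarts, replace = TRUE)
    })
    for (r in seq_len(restarts)) {
        centres <- .farthestPointSeed(traj, k, firsts[r], metric)
        run <- .lloyd(traj, traj[centres, , drop = FALSE], metric, maxIter)
        if (is.null(best) || run$total < best$total) best <- run
    }
    sizes <- tabulate(best$assignment, nbins = k)
    rownames(best$centroids) <- NULL
    assignments <- best$assignment
    names(assignments) <- rownames(traj)
    methods::new("TrendClusterSet",
                 assignments = assignments,
                 centroids = best$centroids,
                 sizes = as.integer(sizes),
                 inclinations = rep(NA_character_, k),
                 trajectories = traj,
                 ageGrid = as.numeric(ageGrid),
                 metric = metric, seed = as.integer(seed))
}

#' @describeIn kmeansTrends per-probe cluster index (NA once removed).
#' @param x a `TrendClusterSet`.
#' @export
setMethod("clusterAssignments", "TrendClusterSet", function(x) x@assignments)

#' @describeIn kmeansTrends cluster-by-grid centroid matrix.
#' @export
setMethod("centroids", "TrendClusterSet", function(x) x@centroids)

#' @describeIn kmeansTrends member count per cluster.
#' @export
setMethod("clusterSizes", "TrendClusterSet", function(x) x@sizes)

#' @describeIn kmeansTrends inclination label per cluster.
#' @export
setMethod("inclinations", "TrendClusterSet", function(x) x@inclinations)

setMethod("show", "TrendClusterSet", function(object) {
    cat("TrendClusterSet:", length(object@sizes), "clusters of",
        length(object@assignments), "trajectories",
        sprintf("(%s metric)\n", object@metric))
    lab <- ifelse(is.na(object@inclinations), "", object@inclinations)
    for (j in seq_along(object@sizes))
        cat(sprintf("  cluster %d: n = %d %s\n", j, object@sizes[j], lab[j]))
    invisible(NULL)
})

#' Merge redundant clusters and drop singletons
#'
#' Iteratively merges the pair of clusters whose centroid Pearson
#' correlation is highest while at or above `corrThreshold`, recomputing the
#' merged centroid as the mean of all member trajectories, until no pair
#' qualifies; clusters of size 1 are then removed (their probes become
#' unassigned). The threshold is on the signed correlation, so opposite
#' trends are never merged.
#'
#' @param clusters a [TrendClusterSet-class].
#' @param corrThreshold merge threshold on signed centroid correlation
#'   (default 0.9).
#' @return A [TrendClusterSet-class] with clusters renumbered 1..K.
#' @export
mergeRedundantClusters <- function(clusters, corrThreshold = 0.9) {
    traj <- clusters@trajectories
    assign <- clusters@assignments
    cents <- clusters@centroids
    live <- which(clusters@sizes > 0L)
    repeat {
        if (length(live) < 2L) break
        cc <- stats::cor(t(cents[live, , drop = FALSE]))
        diag(cc) <- -Inf
        if (max(cc) < corrThreshold) break
        idx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
        a <- live[idx[1]]; b <- live[idx[2]]
        assign[assign == b] <- a
        cents[a, ] <- colMeans(traj[assign == a, , drop = FALSE])
        live <- setdiff(live, b)
    }
    sizes <- vapply(live, function(j) sum(assign == j, na.rm = TRUE), 0L)
    keep <- live[sizes >= 2L]
    assign[!(assign %in% keep)] <- NA_integer_
    newId <- match(assign, keep)
    names(newId) <- names(assign)
    methods::new("TrendClusterSet",
                 assignments = newId,
                 centroids = cents[keep, , drop = FALSE],
                 sizes = vapply(seq_along(keep),
                                function(j) sum(newId == j, na.rm = TRUE), 0L),
                 inclinations = rep(NA_character_, length(keep)),
                 trajectories = traj, ageGrid = clusters@ageGrid,
                 metric = clusters@metric, seed = clusters@seed)
}

#' Label cluster inclinations
#'
#' A cluster is `"positive"` when its centroid's endpoint difference (value
#' at the oldest grid age minus value at the youngest) is positive,
#' `"negative"` when it falls, and `"ambiguous"` when exactly zero
#' (ambiguous clusters are excluded from age-position support).
#'
#' @param clusters a [TrendClusterSet-class].
#' @return The same object with inclinations filled in.
#' @export
labelInclinations <- function(clusters) {
    cents <- clusters@centroids
    d <- cents[, ncol(cents)] - cents[, 1]
    clusters@inclinations <- ifelse(d > 0, "positive",
                                    ifelse(d < 0, "negative", "ambiguous"))
    clusters
}

#' Locate the age-position of a set of trajectories
#'
#' The age-position is the conjunction point between the opposite
#' inclinations of the standardized trajectories. Procedure
#' (`method = "trajectory-crossing"`, the default): (1) cluster under
#' absolute-correlation K-means; (2) within the largest cluster, split
#' members by the sign of their correlation with the centroid; (3) average
#' each sign group into a mean trajectory; (4) report the age at which the
#' two mean trajectories cross, i.e. the grid interval where their
#' difference changes sign, refined by linear interpolation. When several
#' crossings exist the one with the largest absolute slope of the difference
#' is primary and the rest are reported as secondary. The alternative
#' `method = "quadratic-vertex"` returns the vertex `-beta/(2*gamma)` of a
#' quadratic fitted to the sign-aligned (unsigned) mean trajectory.
#'
#' A result with `NA` age (no sign change on the grid, a single-signed
#' support cluster, or a vertex outside the observed range) is reported, not
#' raised as an error.
#'
#' @param trajectories probe-by-grid matrix of standardized trajectories (or
#'   a [ProbeFitResults-class], standardized internally).
#' @param ageGrid grid ages in years (defaults to trajectory column names).
#' @param k,seed,restarts clustering parameters (see [kmeansTrends()]).
#' @param method `"trajectory-crossing"` or `"quadratic-vertex"`.
#' @return An [AgePosition-class].
#' @export
detectAgePosition <- function(trajectories, ageGrid = NULL, k = 10L,
                              seed = 1L, restarts = 5L,
                              method = c("trajectory-crossing",
                                         "quadratic-vertex")) {
    method <- match.arg(method)
    if (methods::is(trajectories, "ProbeFitResults")) {
        if (is.null(ageGrid)) ageGrid <- ageGrid(trajectories)
        trajectories <- standardizeTrajectories(trajectories)
    }
    traj <- as.matrix(trajectories)
    k <- min(k, nrow(traj))
    cl <- kmeansTrends(traj, k = k, metric = "abscor", seed = seed,
                       ageGrid = ageGrid, restarts = restarts)
    grid <- cl@ageGrid
    big <- which.max(cl@sizes)
    members <- traj[cl@assignments == big, , drop = FALSE]
    cc <- drop(stats::cor(t(members), cl@centroids[big, ]))
    pos <- members[cc >= 0, , drop = FALSE]
    neg <- members[cc < 0, , drop = FALSE]
    supp <- c(nrow(pos), nrow(neg))
    noPosition <- function(note)
        methods::new("AgePosition", age = NA_real_, decade = NA_integer_,
                     method = method, clusterId = as.integer(big),
                     secondary = numeric(0), supportSizes = as.integer(supp),
                     note = note)
    if (nrow(pos) == 0L || nrow(neg) == 0L)
        return(noPosition(paste("largest absolute-correlation cluster is",
                                "single-signed; no conjunction point")))
    U <- colMeans(pos)
    D <- colMeans(neg)
    if (method == "quadratic-vertex") {
        aligned <- rbind(pos, -neg)
        mu <- colMeans(aligned)
        qf <- stats::lm.fit(cbind(1, grid, grid^2), mu)$coefficients
        if (qf[3] == 0)
            return(noPosition("aligned mean trajectory has no curvature"))
        vertex <- -qf[2] / (2 * qf[3])
        if (vertex < min(grid) || vertex > max(grid))
            return(noPosition(sprintf(
                "quadratic vertex (%.1f) lies outside the observed age range",
                vertex)))
        return(methods::new("AgePosition", age = unname(vertex),
                            decade = as.integer(floor(vertex / 10) + 1),
                            method = method, clusterId = as.integer(big),
                            secondary = numeric(0),
                            supportSizes = as.integer(supp),
                            note = ""))
    }
    d <- U - D
    flip <- which(d[-1] * d[-length(d)] < 0)
    exact <- which(d == 0)
    crossings <- numeric(0)
    slopes <- numeric(0)
    for (i in flip) {
        s <- (d[i + 1] - d[i]) / (grid[i + 1] - grid[i])
        crossings <- c(crossings, grid[i] - d[i] / s)
        slopes <- c(slopes, s)
    }
    for (i in exact) {
        # an exact grid zero is itself a crossing; slope from neighbours
        lo <- max(i - 1, 1); hi <- min(i + 1, length(d))
        crossings <- c(crossings, grid[i])
        slopes <- c(slopes, (d[hi] - d[lo]) / (grid[hi] - grid[lo]))
    }
    if (!length(crossings))
        return(noPosition("mean trajectories of the two inclinations never cross"))
    ord <- order(abs(slopes), decreasing = TRUE)
    primary <- crossings[ord[1]]
    methods::new("AgePosition", age = unname(primary),
                 decade = as.integer(floor(primary / 10) + 1),
                 method = method, clusterId = as.integer(big),
                 secondary = unname(crossings[ord[-1]]),
                 supportSizes = as.integer(supp), note = "")
}

#' @describeIn detectAgePosition the detected age in years (NA if absent).
#' @param x an `AgePosition` object.
#' @export
setMethod("positionAge", "AgePosition", function(x) x@age)

#' @describeIn detectAgePosition the decade, `floor(age/10) + 1` (the
#'   seventh decade spans ages 60-69).
#' @export
setMethod("positionDecade", "AgePosition", function(x) x@decade)

setMethod("show", "AgePosition", function(object) {
    if (is.na(object@age)) {
        cat("AgePosition: none detected (", object@note, ")\n", sep = "")
    } else {
        cat(sprintf("AgePosition: %.1f years (decade %d), method %s\n",
                    object@age, object@decade, object@method))
        cat(sprintf("  supporting cluster %d, sign groups %d/%d\n",
                    object@clusterId, object@supportSizes[1],
                    object@supportSizes[2]))
        if (length(object@secondary))
            cat("  secondary crossings at",
                paste(sprintf("%.1f", object@secondary), collapse = ", "),
                "\n")
    }
    invisible(NULL)
})
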