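# Shared fixture builders. Everything is generated in code; no data files.

# A tiny cohort with hand-controllable values.
makeTinyDataset <- function(values = matrix(seq_len(12) + 0, 3, 4),
                            ages = c(50, 60, 70, 80)) {
    dimnames(values) <- list(paste0("p", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
    AgeExpressionSet(values, ages = ages)
}

# Write a dataset to TSV files in a temp dir; returns the paths.
writeTinyFiles <- function(values, ages, dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
    dimnames(values) <- list(paste0("p", seq_len(nrow(values))),
                             paste0("s", seq_len(ncol(values))))
    ef <- file.path(dir, "expr.tsv")
    mf <- file.path(dir, "meta.tsv")
    em <- cbind(data.frame(probe_id = rownames(values)),
                as.data.frame(values))
    write.table(em, ef, sep = "\t", quote = FALSE, row.names = FALSE)
    md <- data.frame(sample_id = colnames(values), age = ages)
    write.table(md, mf, sep = "\t", quote = FALSE, row.names = FALSE)
    list(expression = ef, metadata = mf, dir = dir)
}

# Noiseless standardized hinge trajectories on a grid: nUp rising and
# nDown falling, all hinged at `cp`.
makeHingeTrajectories <- function(grid, cp, delta = 1, nUp = 5, nDown = 5,
                                  jitter = 0) {
    hinge <- delta * pmax(0, grid - cp) / (max(grid) - cp)
    traj <- rbind(
        matrix(rep(hinge, nUp), nrow = nUp, ncol = length(grid),
               byrow = TRUE),
        matrix(rep(-hinge, nDown), nrow = nDown, ncol = length(grid),
               byrow = TRUE))
    if (jitter > 0)
        traj <- traj + matrix(rnorm(length(traj), 0, jitter),
                              nrow = nrow(traj))
    rownames(traj) <- paste0("t", seq_len(nrow(traj)))
    colnames(traj) <- as.character(grid)
    traj - rowMeans(traj)
}

# Brute-force BH by the displayed formula: q_(i) = min_{j>=i} p_(j)*m/j.
bruteForceBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    out <- numeric(m)
    out[o] <- q
    out
}

# Brute-force neighbourhood counts by pairwise comparison.
bruteForceCounts <- function(ages, halfwidth) {
    vapply(ages, function(a) sum(abs(ages - a) <= halfwidth), 0L)
}
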