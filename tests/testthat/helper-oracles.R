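# Brute-force oracles for the texture matrices, written independently of the
# package's compiled builders: plain R loops and rle()-based line scans.

# the 13 unique direction vectors (same convention as the package)
DIRS13 <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(-1, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(-1, 0, 1), c(0, 1, 1), c(0, -1, 1),
    c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(-1, -1, 1))

inGrid <- function(p, d) all(p >= 1) && all(p <= d)

# co-occurrence counts by exhaustive voxel-pair enumeration
oracleGlcm <- function(lv, ng, dist = 1L) {
    d <- dim(lv)
    out <- array(0, c(ng, ng, 13))
    for (a in 1:13) {
        off <- DIRS13[a, ] * dist
        for (i in seq_len(d[1])) for (j in seq_len(d[2]))
            for (k in seq_len(d[3])) {
                li <- lv[i, j, k]
                if (li <= 0) next
                q <- c(i, j, k) + off
                if (!inGrid(q, d)) next
                lj <- lv[q[1], q[2], q[3]]
                if (lj <= 0) next
                out[li, lj, a] <- out[li, lj, a] + 1
                out[lj, li, a] <- out[lj, li, a] + 1
            }
    }
    out
}

# run-length counts via rle() over every grid line of each direction
oracleGlrlm <- function(lv, ng) {
    d <- dim(lv)
    lmax <- max(d)
    out <- array(0, c(ng, lmax, 13))
    for (a in 1:13) {
        off <- DIRS13[a, ]
        starts <- list()
        for (i in seq_len(d[1])) for (j in seq_len(d[2]))
            for (k in seq_len(d[3])) {
                p <- c(i, j, k)
                if (!inGrid(p - off, d)) starts[[length(starts) + 1L]] <- p
            }
        for (p0 in starts) {
            line <- integer(0)
            p <- p0
            while (inGrid(p, d)) {
                line <- c(line, lv[p[1], p[2], p[3]])
                p <- p + off
            }
            r <- rle(line)
            for (t in seq_along(r$lengths)) {
                if (r$values[t] > 0)
                    out[r$values[t], r$lengths[t], a] <-
                        out[r$values[t], r$lengths[t], a] + 1
            }
        }
    }
    out
}

# zones via iterative minimum-label propagation over 26-neighbourhoods
oracleGlszm <- function(lv) {
    d <- dim(lv)
    lab <- array(seq_len(prod(d)), d)
    lab[lv <= 0] <- 0L
    repeat {
        changed <- FALSE
        for (i in seq_len(d[1])) for (j in seq_len(d[2]))
            for (k in seq_len(d[3])) {
                if (lv[i, j, k] <= 0) next
                for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
                    if (di == 0 && dj == 0 && dk == 0) next
                    q <- c(i + di, j + dj, k + dk)
                    if (!inGrid(q, d)) next
                    if (lv[q[1], q[2], q[3]] == lv[i, j, k] &&
                        lab[q[1], q[2], q[3]] < lab[i, j, k]) {
                        lab[i, j, k] <- lab[q[1], q[2], q[3]]
                        changed <- TRUE
                    }
                }
            }
        if (!changed) break
    }
    ids <- setdiff(unique(as.vector(lab)), 0L)
    do.call(rbind, lapply(ids, function(z) {
        sel <- lab == z
        c(level = lv[which(sel)[1]], size = sum(sel))
    }))
}

# dependence counts by direct neighbour enumeration
oracleGldm <- function(lv, ng, alpha = 0L, dist = 1L) {
    d <- dim(lv)
    maxDep <- (2 * dist + 1)^3
    out <- matrix(0, ng, maxDep)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
            li <- lv[i, j, k]
            if (li <= 0) next
            dep <- 0L
            for (di in -dist:dist) for (dj in -dist:dist)
                for (dk in -dist:dist) {
                    if (di == 0 && dj == 0 && dk == 0) next
                    q <- c(i + di, j + dj, k + dk)
                    if (!inGrid(q, d)) next
                    lj <- lv[q[1], q[2], q[3]]
                    if (lj > 0 && abs(lj - li) <= alpha) dep <- dep + 1L
                }
            out[li, dep + 1L] <- out[li, dep + 1L] + 1
        }
    out
}

# neighbourhood gray-tone sums by direct enumeration
oracleNgtdm <- function(lv, ng, dist = 1L) {
    d <- dim(lv)
    out <- matrix(0, ng, 2)
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
        for (k in seq_len(d[3])) {
            li <- lv[i, j, k]
            if (li <= 0) next
            nb <- numeric(0)
            for (di in -dist:dist) for (dj in -dist:dist)
                for (dk in -dist:dist) {
                    if (di == 0 && dj == 0 && dk == 0) next
                    q <- c(i + di, j + dj, k + dk)
                    if (!inGrid(q, d)) next
                    lj <- lv[q[1], q[2], q[3]]
                    if (lj > 0) nb <- c(nb, lj)
                }
            if (length(nb)) {
                out[li, 1] <- out[li, 1] + 1
                out[li, 2] <- out[li, 2] + abs(li - mean(nb))
            }
        }
    out
}

# a random small discretized ROI (levels 0..ngmax, at least one ROI voxel)
randomLevels <- function(maxdim = 4L, ngmax = 4L) {
    d <- c(sample(2:maxdim, 1), sample(2:maxdim, 1), sample(1:maxdim, 1))
    lv <- array(sample(0:ngmax, prod(d), replace = TRUE,
                       prob = c(0.25, rep(0.75 / ngmax, ngmax))), d)
    if (all(lv == 0)) lv[1] <- 1L
    lv
}

droiFromLevels <- function(lv, spacing = c(1, 1, 1)) {
    new("DiscretizedRoi", levels = lv, ng = max(lv), spacing = spacing)
}

# normalized count matrices exposed for the probability-normalization check
packageGlcmCounts <- function(lv, ng, dist = 1L)
    PCDRadiomics:::cppGlcmCounts(as.integer(lv), dim(lv), ng, dist)
packageGlrlmCounts <- function(lv, ng)
    PCDRadiomics:::cppGlrlmCounts(as.integer(lv), dim(lv), ng)
packageGlszmZones <- function(lv)
    PCDRadiomics:::cppGlszmZones(as.integer(lv), dim(lv))
packageGldmCounts <- function(lv, ng, alpha = 0L, dist = 1L)
    PCDRadiomics:::cppGldmCounts(as.integer(lv), dim(lv), ng, alpha, dist)
packageNgtdmStats <- function(lv, ng, dist = 1L)
    PCDRadiomics:::cppNgtdmStats(as.integer(lv), dim(lv), ng, dist)

# small cylindrical test mask helper
cylinderMask <- function(dims, diameterPx, layers) {
    ci <- (dims[1] + 1) / 2
    cj <- (dims[2] + 1) / 2
    disk <- outer((seq_len(dims[1]) - ci)^2, (seq_len(dims[2]) - cj)^2,
                  "+") < (diameterPx / 2)^2
    m <- array(FALSE, dims)
    for (k in layers) m[, , k] <- disk
    m
}
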