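#' @include discretize.R utils.R
NULL

# levels present in a discretized ROI
presentLevels <- function(droi) {
    lv <- droi@levels[droi@levels > 0L]
    sort(unique(as.integer(lv)))
}

roiVoxelCount <- function(droi) sum(droi@levels > 0L)

glcmFeatureNames <- c("Autocorrelation", "JointAverage", "ClusterProminence",
    "ClusterShade", "ClusterTendency", "Contrast", "Correlation",
    "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
    "JointEnergy", "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id",
    "Idn", "InverseVariance", "MaximumProbability", "SumAverage",
    "SumEntropy", "SumSquares", "MCC")

# 24 GLCM features from one symmetric co-occurrence count matrix with gray
# level values ivec attached to its rows/columns.
glcmFromMatrix <- function(P, ivec) {
    tot <- sum(P)
    p <- P / tot
    px <- rowSums(p)
    ngp <- length(ivec)
    I <- matrix(ivec, ngp, ngp)
    J <- t(I)
    ux <- sum(ivec * px)
    sigx <- sqrt(sum((ivec - ux)^2 * px))
    dif <- abs(I - J)
    kd <- 0:(max(ivec) - min(ivec))
    pd <- vapply(kd, function(k) sum(p[dif == k]), numeric(1))
    ks <- (2 * min(ivec)):(2 * max(ivec))
    sumIJ <- I + J
    ps <- vapply(ks, function(k) sum(p[sumIJ == k]), numeric(1))
    da <- sum(kd * pd)
    hxy <- -sum(xlog2(p))
    hx <- -sum(xlog2(px))
    pxpy <- outer(px, px)
    sel <- p > 0 & pxpy > 0
    hxy1 <- -sum(p[sel] * log2(pxpy[sel]))
    hxy2 <- -sum(xlog2(pxpy))
    corDeg <- sigx <= .Machine$double.eps^0.5
    mcc <- if (ngp == 1L) 1 else {
        U <- p / px
        V <- sweep(p, 2, px, "/")
        ev <- sort(Re(eigen(U %*% t(V), only.values = TRUE)$values),
                   decreasing = TRUE)
        sqrt(min(1, max(0, ev[2])))
    }
    vals <- c(
        Autocorrelation = sum(I * J * p),
        JointAverage = ux,
        ClusterProminence = sum((I + J - 2 * ux)^4 * p),
        ClusterShade = sum((I + J - 2 * ux)^3 * p),
        ClusterTendency = sum((I + J - 2 * ux)^2 * p),
        Contrast = sum((I - J)^2 * p),
        Correlation = if (corDeg) 1 else
            (sum(I * J * p) - ux^2) / sigx^2,
        DifferenceAverage = da,
        DifferenceEntropy = -sum(xlog2(pd)),
        DifferenceVariance = sum((kd - da)^2 * pd),
        JointEnergy = sum(p^2),
        JointEntropy = hxy,
        Imc1 = if (hx <= 0) 0 else (hxy - hxy1) / hx,
        Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
        Idm = sum(p / (1 + (I - J)^2)),
        Idmn = sum(p / (1 + (dif / ngp)^2)),
        Id = sum(p / (1 + dif)),
        Idn = sum(p / (1 + dif / ngp)),
        InverseVariance = sum(p[dif > 0] / dif[dif > 0]^2),
        MaximumProbability = max(p),
        SumAverage = sum(ks * ps),
        SumEntropy = -sum(xlog2(ps)),
        SumSquares = sum((I - ux)^2 * p),
        MCC = mcc)
    attr(vals, "cor_degenerate") <- corDeg
    vals
}

#' Gray-level co-occurrence features
#'
#' Builds symmetric co-occurrence matrices at the configured voxel offset
#' over the 13 unique 3D directions (4 in-plane directions per slice in 2D
#' mode), normalizes each, computes the 24-feature set and averages every
#' feature over directions. A constant ROI yields the degenerate conventions
#' JointEntropy 0, MaximumProbability 1 and Correlation 1 (flagged).
#'
#' @param droi a [DiscretizedRoi-class].
#' @param settings an [ExtractionSettings-class].
#' @return named numeric vector of 24 features with a `degenerate` attribute.
#' @export
glcmFeatures <- function(droi, settings = extractionSettings()) {
    ivec <- presentLevels(droi)
    counts <- cppGlcmCounts(as.integer(droi@levels), dim(droi@levels),
                            droi@ng, settings@glcmDistance)
    dirs <- if (settings@dimensionality == "twoD_per_slice") 1:4 else 1:13
    acc <- NULL
    nd <- 0L
    corDeg <- FALSE
    for (a in dirs) {
        P <- counts[ivec, ivec, a, drop = FALSE]
        dim(P) <- c(length(ivec), length(ivec))
        if (sum(P) == 0) next
        keep <- rowSums(P) > 0
        v <- glcmFromMatrix(P[keep, keep, drop = FALSE], ivec[keep])
        corDeg <- corDeg || attr(v, "cor_degenerate")
        acc <- if (is.null(acc)) v else acc + v
        nd <- nd + 1L
    }
    if (nd == 0L) { # no voxel pairs at all: single-cell convention
        acc <- glcmFromMatrix(matrix(2, 1, 1), ivec[1])
        corDeg <- TRUE
        nd <- 1L
    }
    vals <- acc / nd
    names(vals) <- glcmFeatureNames
    flags <- setNames(rep(FALSE, length(vals)), names(vals))
    flags["Correlation"] <- corDeg
    flags["MCC"] <- length(ivec) == 1L
    attr(vals, "degenerate") <- flags
    vals
}

glrlmFeatureNames <- c("ShortRunEmphasis", "LongRunEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
    "RunPercentage", "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")

# Shared size-weighted feature kernel of the run-length / size-zone /
# dependence families: counts matrix P over (gray level i, size j).
sizeMatrixFeatures <- function(P, ivec, jvec, np) {
    ns <- sum(P)
    p <- P / ns
    I <- matrix(ivec, length(ivec), length(jvec))
    J <- matrix(jvec, length(ivec), length(jvec), byrow = TRUE)
    mi <- sum(I * p)
    mj <- sum(J * p)
    c(sre = sum(p / J^2),
      lre = sum(p * J^2),
      gln = sum(rowSums(P)^2) / ns,
      glnn = sum(rowSums(P)^2) / ns^2,
      rln = sum(colSums(P)^2) / ns,
      rlnn = sum(colSums(P)^2) / ns^2,
      rp = ns / np,
      glv = sum((I - mi)^2 * p),
      rv = sum((J - mj)^2 * p),
      re = -sum(xlog2(p)),
      lgle = sum(p / I^2),
      hgle = sum(p * I^2),
      srlgle = sum(p / (I^2 * J^2)),
      srhgle = sum(p * I^2 / J^2),
      lrlgle = sum(p * J^2 / I^2),
      lrhgle = sum(p * I^2 * J^2))
}

#' Gray-level run-length features
#'
#' Maximal runs of equal gray level along the 13 unique directions (4
#' in-plane in 2D mode); the 16-feature set is computed per direction and
#' averaged.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 16 features with a `degenerate` attribute.
#' @export
glrlmFeatures <- function(droi, settings = extractionSettings()) {
    ivec <- presentLevels(droi)
    np <- roiVoxelCount(droi)
    counts <- cppGlrlmCounts(as.integer(droi@levels), dim(droi@levels),
                             droi@ng)
    dirs <- if (settings@dimensionality == "twoD_per_slice") 1:4 else 1:13
    acc <- 0
    for (a in dirs) {
        P <- counts[ivec, , a, drop = FALSE]
        dim(P) <- c(length(ivec), dim(counts)[2])
        jmax <- max(which(colSums(P) > 0))
        acc <- acc + sizeMatrixFeatures(P[, 1:jmax, drop = FALSE], ivec,
                                        1:jmax, np)
    }
    vals <- acc / length(dirs)
    names(vals) <- glrlmFeatureNames
    attr(vals, "degenerate") <- setNames(rep(FALSE, 16L), glrlmFeatureNames)
    vals
}

glszmFeatureNames <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
    "ZonePercentage", "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")

#' Gray-level size-zone features
#'
#' Zones are 26-connected components of equal gray level (8-connected within
#' a slice in 2D mode); the 16-feature set is computed from the zone-size
#' matrix without direction averaging.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 16 features with a `degenerate` attribute.
#' @export
glszmFeatures <- function(droi, settings = extractionSettings()) {
    np <- roiVoxelCount(droi)
    zones <- cppGlszmZones(as.integer(droi@levels), dim(droi@levels))
    ivec <- sort(unique(zones[, 1]))
    jvec <- sort(unique(zones[, 2]))
    P <- matrix(0, length(ivec), length(jvec))
    for (r in seq_len(nrow(zones))) {
        i <- match(zones[r, 1], ivec)
        j <- match(zones[r, 2], jvec)
        P[i, j] <- P[i, j] + 1
    }
    vals <- sizeMatrixFeatures(P, ivec, jvec, np)
    names(vals) <- glszmFeatureNames
    attr(vals, "degenerate") <- setNames(rep(FALSE, 16L), glszmFeatureNames)
    vals
}

gldmFeatureNames <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")

#' Gray-level dependence features
#'
#' For every ROI voxel the dependence is the number of neighbours within the
#' configured Chebyshev distance whose gray level differs by at most
#' `gldmAlpha`; the dependence matrix over (level, dependence + 1) yields the
#' 14-feature set.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 14 features with a `degenerate` attribute.
#' @export
gldmFeatures <- function(droi, settings = extractionSettings()) {
    np <- roiVoxelCount(droi)
    P <- cppGldmCounts(as.integer(droi@levels), dim(droi@levels), droi@ng,
                       settings@gldmAlpha, settings@gldmDistance)
    ivec <- presentLevels(droi)
    P <- P[ivec, , drop = FALSE]
    jmax <- max(which(colSums(P) > 0))
    P <- P[, 1:jmax, drop = FALSE]
    full <- sizeMatrixFeatures(P, ivec, 1:jmax, np)
    vals <- c(full[["sre"]], full[["lre"]], full[["gln"]] , full[["rln"]],
              full[["rlnn"]], full[["glv"]], full[["rv"]], full[["re"]],
              full[["lgle"]], full[["hgle"]], full[["srlgle"]],
              full[["srhgle"]], full[["lrlgle"]], full[["lrhgle"]])
    names(vals) <- gldmFeatureNames
    attr(vals, "degenerate") <- setNames(rep(FALSE, 14L), gldmFeatureNames)
    vals
}

ngtdmFeatureNames <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                       "Strength")

# Largest reported Coarseness; returned when the gray-tone differences vanish
NGTDM_COARSENESS_CAP <- 1e6

#' Neighbourhood gray-tone difference features
#'
#' For each gray level i, \eqn{s_i} sums the absolute differences between i
#' and the mean level of each voxel's valid neighbours (Chebyshev distance
#' `ngtdmDistance`). Coarseness, Contrast, Busyness, Complexity and Strength
#' follow the reference definitions; Coarseness is capped at 1e6 (flagged)
#' when the differences vanish, and Contrast/Busyness are 0 for a single
#' gray level.
#'
#' @inheritParams glcmFeatures
#' @return named numeric vector of 5 features with a `degenerate` attribute.
#' @export
ngtdmFeatures <- function(droi, settings = extractionSettings()) {
    S <- cppNgtdmStats(as.integer(droi@levels), dim(droi@levels), droi@ng,
                       settings@ngtdmDistance)
    pres <- which(S[, 1] > 0)
    ni <- S[pres, 1]
    si <- S[pres, 2]
    ivec <- pres
    nvp <- sum(ni)
    p <- ni / nvp
    ngp <- length(pres)
    coarseDen <- sum(p * si)
    coarseDeg <- coarseDen <= 0
    coarseness <- if (coarseDeg) NGTDM_COARSENESS_CAP else
        min(NGTDM_COARSENESS_CAP, 1 / coarseDen)
    if (ngp > 1) {
        I <- matrix(ivec, ngp, ngp)
        J <- t(I)
        PI <- matrix(p, ngp, ngp)
        PJ <- t(PI)
        SI <- matrix(si, ngp, ngp)
        SJ <- t(SI)
        contrast <- sum(PI * PJ * (I - J)^2) / (ngp * (ngp - 1)) *
            sum(si) / nvp
        busyDen <- sum(abs(I * PI - J * PJ))
        busyness <- if (busyDen <= 0) 0 else sum(p * si) / busyDen
        complexity <- sum(abs(I - J) * (PI * SI + PJ * SJ) / (PI + PJ)) / nvp
        strength <- if (sum(si) <= 0) 0 else
            sum((PI + PJ) * (I - J)^2) / sum(si)
    } else {
        contrast <- 0
        busyness <- 0
        complexity <- 0
        strength <- 0
    }
    vals <- c(Coarseness = coarseness, Contrast = contrast,
              Busyness = busyness, Complexity = complexity,
              Strength = strength)
    flags <- setNames(rep(FALSE, 5L), ngtdmFeatureNames)
    flags["Coarseness"] <- coarseDeg
    attr(vals, "degenerate") <- flags
    vals
}
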