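#' @include discretize.R
NULL

firstOrderNames <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
    "Percentile10", "Percentile90", "Maximum", "Mean", "Median",
    "InterquartileRange", "Range", "MeanAbsoluteDeviation",
    "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
    "Kurtosis", "Variance", "Uniformity")

#' First-order intensity features
#'
#' The 18-feature first-order set computed on raw HU values; only Entropy and
#' Uniformity use the fixed-bin-width histogram. Moments use the population
#' convention (denominator N); Kurtosis is not excess-corrected. On a
#' zero-variance ROI, Skewness and Kurtosis are returned as 0 and flagged
#' degenerate.
#'
#' @param values numeric vector of raw HU values inside the ROI.
#' @param voxelVolume voxel volume in mm^3 (for TotalEnergy).
#' @param binWidth histogram bin width in HU (default 25).
#' @return named numeric vector of 18 features with a logical `degenerate`
#'   attribute.
#' @export
firstOrderFeatures <- function(values, voxelVolume, binWidth = 25) {
    if (length(values) == 0L) stop("empty ROI")
    n <- length(values)
    m <- mean(values)
    dev <- values - m
    m2 <- mean(dev^2)
    qs <- quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE,
                   type = 7)
    d <- discretize(values, binWidth)
    p <- tabulate(d$levels, nbins = d$ng) / n
    deg <- m2 <= 0
    robust <- values[values >= qs[1] & values <= qs[5]]
    out <- c(
        Energy = sum(values^2),
        TotalEnergy = voxelVolume * sum(values^2),
        Entropy = -sum(xlog2(p)),
        Minimum = min(values),
        Percentile10 = qs[1],
        Percentile90 = qs[5],
        Maximum = max(values),
        Mean = m,
        Median = qs[3],
        InterquartileRange = qs[4] - qs[2],
        Range = max(values) - min(values),
        MeanAbsoluteDeviation = mean(abs(dev)),
        RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
        RootMeanSquared = sqrt(mean(values^2)),
        Skewness = if (deg) 0 else mean(dev^3) / m2^1.5,
        Kurtosis = if (deg) 0 else mean(dev^4) / m2^2,
        Variance = m2,
        Uniformity = sum(p^2))
    names(out) <- firstOrderNames
    flags <- setNames(rep(FALSE, 18L), firstOrderNames)
    if (deg) flags[c("Skewness", "Kurtosis")] <- TRUE
    attr(out, "degenerate") <- flags
    out
}
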