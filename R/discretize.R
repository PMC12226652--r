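#' @include AllClasses.R
NULL

#' Fixed-bin-width gray-level discretization
#'
#' Maps raw HU values to integer gray levels with the fixed-bin-width rule
#' `level(x) = floor((x - min(x)) / binWidth) + 1`. Bin edges are anchored at
#' the ROI minimum, which makes all discretized-texture features invariant to
#' a constant HU shift.
#'
#' @param values numeric vector of raw HU values (non-empty).
#' @param binWidth bin width in HU, > 0.
#' @return list with `levels` (integer vector, minimum 1) and `ng`
#'   (number of gray levels = maximum level).
#' @examples
#' discretize(c(0, 24.9, 25, 50), 25)$levels  # 1 1 2 3
#' @export
discretize <- function(values, binWidth) {
    if (length(values) == 0L) stop("empty ROI: no values to discretize")
    if (!is.finite(binWidth) || binWidth <= 0) stop("binWidth must be > 0")
    lv <- as.integer(floor((values - min(values)) / binWidth)) + 1L
    list(levels = lv, ng = max(lv))
}

#' Discretize an image ROI into a DiscretizedRoi
#'
#' @param image a [VolumeImage-class].
#' @param mask logical array of the ROI (same dimensions as the image).
#' @param binWidth bin width in HU.
#' @return a [DiscretizedRoi-class] on the bounding box of the mask.
#' @export
discretizeRoi <- function(image, mask, binWidth) {
    stopifnot(is(image, "VolumeImage"))
    if (!identical(dim(mask), dim(image@values)))
        stop("geometry error: mask dimensions must match the image")
    if (!any(mask)) stop("empty ROI mask")
    d <- dim(mask)
    lin <- which(mask) - 1L
    i <- lin %% d[1]
    j <- (lin %/% d[1]) %% d[2]
    k <- lin %/% (d[1] * d[2])
    rng <- cbind(range(i), range(j), range(k)) + 1L
    sub <- image@values[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                        rng[1, 3]:rng[2, 3], drop = FALSE]
    msk <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                rng[1, 3]:rng[2, 3], drop = FALSE]
    d <- discretize(sub[msk], binWidth)
    lv <- array(0L, dim = dim(sub))
    lv[msk] <- d$levels
    new("DiscretizedRoi", levels = lv, ng = as.integer(d$ng),
        spacing = image@spacing)
}
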