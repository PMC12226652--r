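#' @include firstorder.R texturefeatures.R
NULL

#' Names and families of the 93-feature set
#'
#' The fixed, documented column order of every feature table: 18 first-order,
#' 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features. Shape features
#' are deliberately not part of the set.
#'
#' @return `featureNames93()` a character vector of 93 `family_Feature`
#'   names; `featureFamilies93()` the corresponding family of each entry.
#' @export
featureNames93 <- function() {
    c(paste0("firstorder_", firstOrderNames),
      paste0("glcm_", glcmFeatureNames),
      paste0("glrlm_", glrlmFeatureNames),
      paste0("glszm_", glszmFeatureNames),
      paste0("gldm_", gldmFeatureNames),
      paste0("ngtdm_", ngtdmFeatureNames))
}

#' @rdname featureNames93
#' @export
featureFamilies93 <- function() {
    rep(c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"),
        times = c(18L, 24L, 16L, 16L, 14L, 5L))
}

# texture families for one DiscretizedRoi (75 values + flags)
textureFeatureBlock <- function(droi, settings) {
    parts <- list(glcm = glcmFeatures(droi, settings),
                  glrlm = glrlmFeatures(droi, settings),
                  glszm = glszmFeatures(droi, settings),
                  gldm = gldmFeatures(droi, settings),
                  ngtdm = ngtdmFeatures(droi, settings))
    vals <- unlist(lapply(names(parts), function(f)
        setNames(as.numeric(parts[[f]]), paste0(f, "_", names(parts[[f]])))))
    flags <- unlist(lapply(names(parts), function(f)
        setNames(attr(parts[[f]], "degenerate"),
                 paste0(f, "_", names(parts[[f]])))))
    list(values = vals, flags = flags)
}

#' Extract the 93-feature vector of one ROI
#'
#' Concatenates the six feature families (18 + 24 + 16 + 16 + 14 + 5 = 93)
#' computed on the raw HU values inside the mask. No resampling, filtering or
#' normalization is applied before extraction, so voxel-size effects flow
#' directly into the features — the phenomenon under study. In
#' `twoD_per_slice` mode the texture families are computed per slice with
#' in-plane directions and averaged over slices.
#'
#' @param image a [VolumeImage-class].
#' @param mask logical array of the ROI, same dimensions as the image.
#' @param settings an [ExtractionSettings-class].
#' @return named numeric vector of 93 features, with attributes `family` and
#'   `degenerate`.
#' @examples
#' img <- volumeImage(array(rnorm(8^3, 50, 20), c(8, 8, 8)), c(1, 1, 1))
#' mask <- array(TRUE, c(8, 8, 8))
#' fv <- extractFeatureVector(img, mask)
#' length(fv)  # 93
#' @export
extractFeatureVector <- function(image, mask,
                                 settings = extractionSettings()) {
    stopifnot(is(image, "VolumeImage"))
    if (!identical(dim(mask), dim(image@values)))
        stop("geometry error: mask dimensions must match the image")
    if (!any(mask)) stop("empty ROI mask")
    x <- image@values[mask]
    fo <- firstOrderFeatures(x, prod(image@spacing), settings@binWidth)
    droi <- discretizeRoi(image, mask, settings@binWidth)
    if (settings@dimensionality == "twoD_per_slice") {
        nz <- dim(droi@levels)[3]
        accV <- 0
        accF <- NULL
        nsl <- 0L
        for (k in seq_len(nz)) {
            lv <- droi@levels[, , k, drop = FALSE]
            if (!any(lv > 0L)) next
            sub <- new("DiscretizedRoi",
                       levels = array(lv, dim = c(dim(lv)[1:2], 1L)),
                       ng = max(lv), spacing = droi@spacing)
            blk <- textureFeatureBlock(sub, settings)
            accV <- accV + blk$values
            accF <- if (is.null(accF)) blk$flags else accF | blk$flags
            nsl <- nsl + 1L
        }
        tex <- list(values = accV / nsl, flags = accF)
    } else {
        tex <- textureFeatureBlock(droi, settings)
    }
    vals <- c(setNames(as.numeric(fo), paste0("firstorder_", names(fo))),
              tex$values)
    flags <- c(setNames(attr(fo, "degenerate"),
                        paste0("firstorder_", firstOrderNames)), tex$flags)
    stopifnot(identical(names(vals), featureNames93()))
    attr(vals, "family") <- featureFamilies93()
    attr(vals, "degenerate") <- unname(flags)
    vals
}
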