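#' @include AllClasses.R
NULL

#' Accessors for VolumeImage
#'
#' @param x a [VolumeImage-class].
#' @return `volValues()` the 3D HU array, `volSpacing()` the mm spacing,
#'   `volOrigin()` the mm position of the first voxel centre.
#' @name VolumeImage-accessors
NULL

#' @rdname VolumeImage-accessors
#' @export
setGeneric("volValues", function(x) standardGeneric("volValues"))
#' @rdname VolumeImage-accessors
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))
#' @rdname VolumeImage-accessors
#' @export
setGeneric("volOrigin", function(x) standardGeneric("volOrigin"))

#' @rdname VolumeImage-accessors
setMethod("volValues", "VolumeImage", function(x) x@values)
#' @rdname VolumeImage-accessors
setMethod("volSpacing", "VolumeImage", function(x) x@spacing)
#' @rdname VolumeImage-accessors
setMethod("volOrigin", "VolumeImage", function(x) x@origin)

setMethod("show", "VolumeImage", function(object) {
    d <- dim(object@values)
    cat(sprintf("VolumeImage %d x %d x %d, spacing %.4g x %.4g x %.4g mm\n",
        d[1], d[2], d[3], object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  HU range [%.1f, %.1f]\n",
        min(object@values), max(object@values)))
})

setMethod("show", "PhantomLayout", function(object) {
    cat(sprintf("PhantomLayout: %d inserts (diameter %.0f mm) in a %.0f mm FOV\n",
        nrow(object@materials), object@insertDiameter, object@fov))
    cat(sprintf("  ground-truth grid %.3g mm, slab %.0f mm, background %.0f HU\n",
        object@fineSpacing, object@slabThickness, object@backgroundHU))
})

setMethod("show", "PhantomGroundTruth", function(object) {
    cat(sprintf("PhantomGroundTruth: %d insert patches, seed %d\n",
        length(object@patches), object@seed))
})

setMethod("show", "RigidTransform", function(object) {
    cat(sprintf("RigidTransform: t = (%.2f, %.2f, %.2f) mm, rotZ = %.2f deg\n",
        object@translation[1], object@translation[2], object@translation[3],
        object@rotationZ))
})

setMethod("show", "RoiSet", function(object) {
    cat(sprintf("RoiSet: %d cylinders, %g px diameter x %d layers\n",
        length(object@materialLabels), object@diameterPx, object@nLayers))
})

setMethod("show", "ExtractionSettings", function(object) {
    cat(sprintf(paste0("ExtractionSettings: bin width %g HU, GLCM distance %d, ",
        "GLDM alpha %d, %s\n"), object@binWidth, object@glcmDistance,
        object@gldmAlpha, object@dimensionality))
})

setMethod("show", "StudyConfig", function(object) {
    cat(sprintf("StudyConfig: %d materials x %d protocols, ROI %g px x %d layers\n",
        nrow(object@layout@materials), nrow(object@protocols),
        object@roiDiameterPx, object@roiLayers))
})

setMethod("show", "RobustnessSummary", function(object) {
    cat("RobustnessSummary\n")
    cat(sprintf("  %d features; %d factor comparisons; %d materials\n",
        object@meta$n_features,
        length(unique(object@factorReliability$factor)),
        length(unique(object@materialVariability$material_label))))
})

#' Layout accessors
#'
#' @param x a [PhantomLayout-class].
#' @return `layoutMaterials()` the material table; `insertCenters()` the
#'   n x 3 matrix of insert centres in mm.
#' @name PhantomLayout-accessors
NULL

#' @rdname PhantomLayout-accessors
#' @export
setGeneric("layoutMaterials", function(x) standardGeneric("layoutMaterials"))
#' @rdname PhantomLayout-accessors
setMethod("layoutMaterials", "PhantomLayout", function(x) x@materials)

#' @rdname PhantomLayout-accessors
#' @export
setGeneric("insertCenters", function(x) standardGeneric("insertCenters"))
#' @rdname PhantomLayout-accessors
setMethod("insertCenters", "PhantomLayout", function(x) x@insertCenters)

#' Extract one binary ROI mask from a RoiSet
#'
#' @param x a [RoiSet-class].
#' @param label material label.
#' @return logical 3D array.
#' @export
setGeneric("roiMask", function(x, label) standardGeneric("roiMask"))

#' @rdname roiMask
setMethod("roiMask", "RoiSet", function(x, label) x@labels == as.integer(label))
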