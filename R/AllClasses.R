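#' @include PCDRadiomics-package.R
NULL

#' VolumeImage: a 3D scalar grid in Hounsfield units
#'
#' The unit every perturbation and extraction step operates on: a dense 3D
#' array of HU values with voxel spacing (mm) and the physical position of the
#' centre of the first voxel (mm).
#'
#' @slot values 3D numeric array (HU).
#' @slot spacing numeric length-3 voxel spacing in mm, all positive.
#' @slot origin numeric length-3 physical coordinate (mm) of the centre of
#'   voxel (1,1,1).
#' @export
setClass("VolumeImage",
    representation(values = "array", spacing = "numeric", origin = "numeric"),
    prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VolumeImage", function(object) {
    d <- dim(object@values)
    if (length(d) != 3L || any(d < 1L)) return("values must be a non-empty 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) return("spacing must be 3 positive numbers (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        return("origin must be 3 finite numbers (mm)")
    TRUE
})

#' Construct a VolumeImage
#'
#' @param values 3D numeric array of HU values.
#' @param spacing voxel spacing in mm (length 3).
#' @param origin physical position (mm) of the centre of the first voxel.
#' @return a [VolumeImage-class] object.
#' @export
volumeImage <- function(values, spacing, origin = c(0, 0, 0)) {
    new("VolumeImage", values = values, spacing = as.numeric(spacing),
        origin = as.numeric(origin))
}

#' PhantomLayout: geometry and material table of the texture phantom
#'
#' @slot materials data.frame with one row per insert: `label`, `name`,
#'   `family` (homogeneous/granular/fibrous/porous), `mean_hu`, `texture_sd`,
#'   `correlation_length` (mm), `kvp_factor` (contrast multiplier at 140 kVp).
#' @slot insertCenters numeric matrix (n x 3) of insert centres in mm,
#'   phantom coordinates (isocentre at the origin).
#' @slot insertDiameter insert diameter in mm.
#' @slot fineSpacing isotropic ground-truth grid spacing in mm.
#' @slot fov scan field of view of the layout in mm.
#' @slot backgroundHU HU value of the supporting foam.
#' @slot slabThickness longitudinal extent of the phantom slab in mm.
#' @export
setClass("PhantomLayout",
    representation(materials = "data.frame", insertCenters = "matrix",
        insertDiameter = "numeric", fineSpacing = "numeric", fov = "numeric",
        backgroundHU = "numeric", slabThickness = "numeric"))

setValidity("PhantomLayout", function(object) {
    m <- object@materials
    need <- c("label", "name", "family", "mean_hu", "texture_sd",
              "correlation_length", "kvp_factor")
    if (!all(need %in% names(m))) return("materials table is missing columns")
    if (anyDuplicated(m$label)) return("material labels must be unique")
    if (any(m$texture_sd < 0)) return("texture_sd must be >= 0")
    if (any(m$correlation_length <= 0)) return("correlation_length must be > 0")
    if (nrow(object@insertCenters) != nrow(m))
        return("insert count must equal material count")
    r <- object@insertDiameter / 2
    cen <- object@insertCenters
    if (any(sqrt(cen[, 1]^2 + cen[, 2]^2) + r > object@fov / 2))
        return("all inserts must lie inside the FOV circle")
    if (nrow(cen) > 1) {
        dxy <- as.matrix(dist(cen[, 1:2]))
        diag(dxy) <- Inf
        if (any(dxy < object@insertDiameter))
            return("inserts must be pairwise non-overlapping")
    }
    if (object@fineSpacing <= 0) return("fineSpacing must be > 0")
    TRUE
})

#' PhantomGroundTruth: fine-grid texture patches for every insert
#'
#' The ground-truth phantom realisation for one study seed. Each insert is
#' held as a fine-grid [VolumeImage-class] patch (the texture cylinder on a
#' constant foam background); the phantom outside the inserts is uniform foam,
#' so a dense whole-FOV array is only materialised on demand via
#' [groundTruthVolume()].
#'
#' @slot layout the [PhantomLayout-class] the truth was generated from.
#' @slot patches named list of per-insert fine-grid VolumeImage patches
#'   (names are material labels).
#' @slot seed integer seed the realisation was generated with.
#' @export
setClass("PhantomGroundTruth",
    representation(layout = "PhantomLayout", patches = "list", seed = "integer"))

setValidity("PhantomGroundTruth", function(object) {
    if (length(object@patches) != nrow(object@layout@materials))
        return("one patch per material is required")
    if (!all(vapply(object@patches, is, logical(1), "VolumeImage")))
        return("patches must be VolumeImage objects")
    TRUE
})

#' RigidTransform: phantom repositioning
#'
#' Maps phantom coordinates to scanner coordinates: rotation about the
#' scanner z axis followed by a translation.
#'
#' @slot translation numeric length-3 translation in mm.
#' @slot rotationZ rotation about z in degrees.
#' @export
setClass("RigidTransform",
    representation(translation = "numeric", rotationZ = "numeric"),
    prototype(translation = c(0, 0, 0), rotationZ = 0))

setValidity("RigidTransform", function(object) {
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
        return("translation must be 3 finite numbers (mm)")
    if (length(object@rotationZ) != 1L || !is.finite(object@rotationZ))
        return("rotationZ must be a finite scalar (degrees)")
    TRUE
})

#' Construct a rigid transform
#'
#' @param translation translation in mm (length 3).
#' @param rotationZ rotation about the z axis in degrees.
#' @return a [RigidTransform-class]; `rigidTransform()` is the identity.
#' @export
rigidTransform <- function(translation = c(0, 0, 0), rotationZ = 0) {
    new("RigidTransform", translation = as.numeric(translation),
        rotationZ = as.numeric(rotationZ))
}

#' RoiSet: cylindrical regions of interest on a protocol grid
#'
#' One circular disk of fixed pixel diameter per material, replicated over the
#' middle slices to form a cylinder. Disk membership is evaluated from the
#' continuous (sub-voxel) centre so that rigidly propagated ROIs cover the
#' same physical region as the reference ROIs.
#'
#' @slot labels integer 3D array; 0 = background, otherwise material label.
#' @slot centers numeric matrix (n x 3): continuous voxel coordinates of each
#'   ROI centre (in-plane) and the central slice index.
#' @slot materialLabels integer vector of material labels (row order of
#'   `centers`).
#' @slot diameterPx disk diameter in pixels.
#' @slot nLayers number of slices in each cylinder.
#' @slot spacing voxel spacing (mm) of the protocol grid.
#' @slot zOffset longitudinal offset (mm) of the slice lattice (the z
#'   component of the scan's rigid transform).
#' @export
setClass("RoiSet",
    representation(labels = "array", centers = "matrix",
        materialLabels = "integer", diameterPx = "numeric",
        nLayers = "integer", spacing = "numeric", zOffset = "numeric"),
    prototype(zOffset = 0))

setValidity("RoiSet", function(object) {
    if (length(dim(object@labels)) != 3L) return("labels must be a 3D array")
    if (nrow(object@centers) != length(object@materialLabels))
        return("one centre per material label")
    if (object@diameterPx < 3 || object@diameterPx %% 2 != 1)
        return("diameterPx must be odd and >= 3")
    TRUE
})

#' DiscretizedRoi: gray-level discretized ROI voxels on their grid
#'
#' @slot levels integer 3D array of gray levels 1..Ng inside the ROI and 0
#'   outside.
#' @slot ng number of gray levels (the maximum level).
#' @slot spacing voxel spacing in mm.
#' @export
setClass("DiscretizedRoi",
    representation(levels = "array", ng = "integer", spacing = "numeric"))

setValidity("DiscretizedRoi", function(object) {
    lv <- object@levels[object@levels > 0L]
    if (length(lv) == 0L) return("ROI must contain at least one voxel")
    if (min(lv) < 1L) return("in-ROI levels must be >= 1")
    if (max(lv) > object@ng) return("ng must be at least the maximum level")
    TRUE
})

#' ExtractionSettings: parameters of the radiomics extractor
#'
#' @slot binWidth fixed bin width in HU for gray-level discretization.
#' @slot glcmDistance co-occurrence offset in voxels.
#' @slot gldmAlpha gray-level similarity tolerance of the dependence matrix.
#' @slot gldmDistance Chebyshev neighbourhood radius of the dependence matrix.
#' @slot ngtdmDistance Chebyshev neighbourhood radius of the gray-tone
#'   difference matrix.
#' @slot aggregation direction aggregation rule (average over the 13 unique
#'   3D directions).
#' @slot dimensionality `"threeD"` (default) or `"twoD_per_slice"`.
#' @export
setClass("ExtractionSettings",
    representation(binWidth = "numeric", glcmDistance = "integer",
        gldmAlpha = "integer", gldmDistance = "integer",
        ngtdmDistance = "integer", aggregation = "character",
        dimensionality = "character"),
    prototype(binWidth = 25, glcmDistance = 1L, gldmAlpha = 0L,
        gldmDistance = 1L, ngtdmDistance = 1L,
        aggregation = "average_over_directions", dimensionality = "threeD"))

setValidity("ExtractionSettings", function(object) {
    if (object@binWidth <= 0) return("binWidth must be > 0")
    if (object@glcmDistance < 1L || object@gldmDistance < 1L ||
        object@ngtdmDistance < 1L) return("distances must be >= 1")
    if (!object@aggregation %in% "average_over_directions")
        return("unsupported aggregation")
    if (!object@dimensionality %in% c("threeD", "twoD_per_slice"))
        return("unsupported dimensionality")
    TRUE
})

#' Construct extraction settings
#'
#' @param binWidth fixed bin width in HU (default 25).
#' @param glcmDistance GLCM offset in voxels (default 1).
#' @param gldmAlpha GLDM gray-level tolerance (default 0).
#' @param gldmDistance GLDM neighbourhood radius in voxels (default 1).
#' @param ngtdmDistance NGTDM neighbourhood radius in voxels (default 1).
#' @param dimensionality `"threeD"` or `"twoD_per_slice"`.
#' @return an [ExtractionSettings-class] object.
#' @export
extractionSettings <- function(binWidth = 25, glcmDistance = 1L, gldmAlpha = 0L,
                               gldmDistance = 1L, ngtdmDistance = 1L,
                               dimensionality = "threeD") {
    new("ExtractionSettings", binWidth = binWidth,
        glcmDistance = as.integer(glcmDistance), gldmAlpha = as.integer(gldmAlpha),
        gldmDistance = as.integer(gldmDistance),
        ngtdmDistance = as.integer(ngtdmDistance),
        dimensionality = dimensionality)
}

#' FeatureTable: 93 features over protocol x material
#'
#' A [SummarizedExperiment::SummarizedExperiment] with features as rows
#' (rowData: `family`) and one column per (protocol, material) combination
#' (colData: `protocol_id`, `material_label`, `material_name`). Assays:
#' `values` (numeric) and `degenerate` (logical flags). Extraction settings,
#' master seed and a settings hash live in `metadata()`.
#'
#' @export
setClass("FeatureTable", contains = "SummarizedExperiment")

#' StudyConfig: everything a full study run needs
#'
#' @slot layout a [PhantomLayout-class].
#' @slot protocols protocol suite data.frame (see [defaultProtocolSuite()]).
#' @slot settings an [ExtractionSettings-class].
#' @slot physics list of image-domain surrogate parameters (see
#'   [defaultPhysics()]).
#' @slot roiDiameterPx ROI disk diameter in pixels.
#' @slot roiLayers number of ROI slices.
#' @export
setClass("StudyConfig",
    representation(layout = "PhantomLayout", protocols = "data.frame",
        settings = "ExtractionSettings", physics = "list",
        roiDiameterPx = "numeric", roiLayers = "integer"))

setValidity("StudyConfig", function(object) {
    if (!"reference" %in% object@protocols$id)
        return("protocol suite must contain the reference protocol")
    if (object@roiLayers < 1L) return("roiLayers must be >= 1")
    TRUE
})

#' RobustnessSummary: study-level robustness tables
#'
#' @slot factorReliability data.frame of per-factor ICC/CCC summaries with
#'   interpretation-bin percentages.
#' @slot factorVariability data.frame of per-factor CV/QCD summaries.
#' @slot materialVariability data.frame of per-material CV/QCD summaries
#'   across all protocols.
#' @slot pooled list of pooled mean/SD and median/IQR blocks.
#' @slot meta list: feature count, thresholds, provenance.
#' @export
setClass("RobustnessSummary",
    representation(factorReliability = "data.frame",
        factorVariability = "data.frame", materialVariability = "data.frame",
        pooled = "list", meta = "list"))
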