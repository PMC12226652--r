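#' @include AllClasses.R texture.R
NULL

# Physical half-extent (mm) of an insert patch beyond the insert radius;
# covers ROI margins, PSF support and the repositioning shift.
PATCH_MARGIN_MM <- 4

#' Generate the ground-truth phantom realisation
#'
#' Fills each insert of the layout with its material texture on the fine
#' isotropic grid and keeps the result as one fine-grid patch per insert on a
#' constant foam background. The realisation is generated once per study seed
#' and shared by every simulated protocol, mirroring a physical phantom that
#' is kept unchanged between scans.
#'
#' @param layout a [PhantomLayout-class].
#' @param seed integer master seed; per-insert seeds are derived
#'   deterministically from it.
#' @return a [PhantomGroundTruth-class].
#' @examples
#' lay <- buildDefaultLayout()
#' gt <- generateGroundTruth(lay, seed = 7)
#' @export
generateGroundTruth <- function(layout, seed) {
    stopifnot(is(layout, "PhantomLayout"))
    validObject(layout)
    mats <- layout@materials
    sp <- layout@fineSpacing
    half <- layout@insertDiameter / 2 + PATCH_MARGIN_MM
    nxy <- 2L * as.integer(ceiling(half / sp)) # even count, centre between voxels
    nz <- as.integer(round(layout@slabThickness / sp))
    rIns <- layout@insertDiameter / 2
    patches <- vector("list", nrow(mats))
    names(patches) <- as.character(mats$label)
    for (r in seq_len(nrow(mats))) {
        m <- mats[r, ]
        tex <- materialTexture(m, c(nxy, nxy, nz), sp,
                               deriveSeed(seed, 10000 + m$label))
        cen <- layout@insertCenters[r, ]
        origin <- c(cen[1] - (nxy - 1) / 2 * sp,
                    cen[2] - (nxy - 1) / 2 * sp,
                    -(nz - 1) / 2 * sp)
        gx <- origin[1] + (seq_len(nxy) - 1) * sp - cen[1]
        gy <- origin[2] + (seq_len(nxy) - 1) * sp - cen[2]
        inside <- outer(gx^2, gy^2, "+") <= rIns^2
        vals <- tex@values
        vals[!array(inside, dim = c(nxy, nxy, nz))] <- layout@backgroundHU
        patches[[r]] <- volumeImage(vals, rep(sp, 3), origin)
    }
    new("PhantomGroundTruth", layout = layout, patches = patches,
        seed = as.integer(seed))
}

#' Densify the ground truth to a whole-FOV volume or label mask
#'
#' Samples the per-insert fine patches (trilinear) onto a regular grid
#' covering the layout FOV, with foam everywhere else. Intended for NIfTI
#' export and visual checks; the study pipeline itself works on the patches.
#'
#' @param truth a [PhantomGroundTruth-class].
#' @param spacing isotropic output spacing in mm (default 1).
#' @return `groundTruthVolume()` a [VolumeImage-class] of HU values;
#'   `groundTruthLabels()` a VolumeImage of material labels (0 background).
#' @export
groundTruthVolume <- function(truth, spacing = 1) {
    .densifyTruth(truth, spacing, labels = FALSE)
}

#' @rdname groundTruthVolume
#' @export
groundTruthLabels <- function(truth, spacing = 1) {
    .densifyTruth(truth, spacing, labels = TRUE)
}

.densifyTruth <- function(truth, spacing, labels) {
    stopifnot(is(truth, "PhantomGroundTruth"))
    layout <- truth@layout
    fov <- layout@fov
    nxy <- as.integer(floor(fov / spacing))
    nz <- max(1L, as.integer(floor(layout@slabThickness / spacing)))
    x <- -fov / 2 + (seq_len(nxy) - 0.5) * spacing
    z <- (seq_len(nz) - (nz + 1) / 2) * spacing
    out <- array(if (labels) 0L else layout@backgroundHU, dim = c(nxy, nxy, nz))
    rIns <- layout@insertDiameter / 2
    for (r in seq_len(nrow(layout@materials))) {
        cen <- layout@insertCenters[r, ]
        lab <- layout@materials$label[r]
        ix <- which(abs(x - cen[1]) <= rIns)
        iy <- which(abs(x - cen[2]) <= rIns)
        if (!length(ix) || !length(iy)) next
        sub <- expand.grid(i = ix, j = iy)
        d2 <- (x[sub$i] - cen[1])^2 + (x[sub$j] - cen[2])^2
        sub <- sub[d2 <= rIns^2, , drop = FALSE]
        if (!nrow(sub)) next
        for (k in seq_len(nz)) {
            if (labels) {
                out[cbind(sub$i, sub$j, k)] <- lab
            } else {
                patch <- truth@patches[[as.character(lab)]]
                pts <- cbind(x[sub$i], x[sub$j], z[k])
                out[cbind(sub$i, sub$j, k)] <- cppTrilinear(
                    as.numeric(patch@values), dim(patch@values),
                    patch@origin, patch@spacing, pts)
            }
        }
    }
    volumeImage(out, rep(spacing, 3),
                c(x[1], x[1], z[1]))
}
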