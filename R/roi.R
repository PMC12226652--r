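#' @include AllClasses.R acquisition.R
NULL

# In-plane disk membership around a continuous voxel-coordinate centre.
# Returns a logical matrix over the index grid iIdx x jIdx.
diskMembership <- function(iIdx, jIdx, ci, cj, diameterPx) {
    r2 <- (diameterPx / 2)^2
    outer((iIdx - ci)^2, (jIdx - cj)^2, "+") < r2
}

#' Build the cylindrical ROIs of every material on a protocol grid
#'
#' Places one circular disk of `diameterPx` pixels (pixel-defined, so the
#' physical size shrinks on the 350 mm high-pitch grid) at each insert centre
#' mapped through the rigid transform, and replicates it over the middle
#' `nLayers` slices. Disk membership is computed from the continuous centre,
#' so ROIs propagated with the true transform cover the same physical region
#' as the reference ROIs.
#'
#' @param protocol one protocol row.
#' @param layout a [PhantomLayout-class].
#' @param transform the scan's rigid transform (identity except reposition).
#' @param diameterPx disk diameter in pixels, odd and >= 3 (default 35).
#' @param nLayers number of cylinder slices (default 25).
#' @return a [RoiSet-class] on the full protocol grid.
#' @examples
#' rois <- buildRois(getProtocol(defaultProtocolSuite(), "reference"),
#'                   buildDefaultLayout())
#' @export
buildRois <- function(protocol, layout, transform = rigidTransform(),
                      diameterPx = 35, nLayers = 25) {
    stopifnot(is(layout, "PhantomLayout"), is(transform, "RigidTransform"))
    if (diameterPx < 3 || diameterPx %% 2 != 1)
        stop("diameterPx must be odd and >= 3")
    s <- pixelSpacing(protocol)
    nxy <- protocol$matrix_size
    dz <- protocol$slice_thickness
    nz <- max(1L, as.integer(floor(layout@slabThickness / dz)))
    if (nLayers > nz)
        stop("nLayers (", nLayers, ") exceeds the protocol slab (", nz, " slices)")
    zVals <- -nz * dz / 2 + (seq_len(nz) - 0.5) * dz + transform@translation[3]
    labels <- array(0L, dim = c(nxy, nxy, nz))
    cents <- matrix(0, nrow(layout@materials), 3)
    labs <- as.integer(layout@materials$label)
    rPhys <- diameterPx / 2 * s
    for (r in seq_len(nrow(layout@materials))) {
        tc <- applyTransform(transform, matrix(c(layout@insertCenters[r, ]), 1, 3))
        # continuous voxel coordinate of the centre
        ci <- (tc[1] + protocol$fov / 2) / s + 0.5
        cj <- (tc[2] + protocol$fov / 2) / s + 0.5
        half <- ceiling(diameterPx / 2) + 1L
        iIdx <- seq(floor(ci) - half, ceiling(ci) + half)
        jIdx <- seq(floor(cj) - half, ceiling(cj) + half)
        if (min(iIdx) < 1 || max(iIdx) > nxy || min(jIdx) < 1 || max(jIdx) > nxy)
            stop("geometry error: ROI for material ", labs[r],
                 " falls outside the image grid")
        if (rPhys > layout@insertDiameter / 2) {
            ov <- (layout@insertDiameter / 2)^2 / rPhys^2
            warning(sprintf(
                "ROI for material %d exceeds its insert (overlap fraction %.2f)",
                labs[r], ov))
        }
        kc <- which.min(abs(zVals - tc[3]))
        kIdx <- kc + seq(-(nLayers - 1) %/% 2, nLayers %/% 2)
        if (min(kIdx) < 1 || max(kIdx) > nz)
            stop("geometry error: ROI slices for material ", labs[r],
                 " fall outside the slab")
        disk <- diskMembership(iIdx, jIdx, ci, cj, diameterPx)
        sel <- which(disk, arr.ind = TRUE)
        for (k in kIdx)
            labels[cbind(iIdx[sel[, 1]], jIdx[sel[, 2]], k)] <- labs[r]
        cents[r, ] <- c(ci, cj, kc)
    }
    new("RoiSet", labels = labels, centers = cents, materialLabels = labs,
        diameterPx = diameterPx, nLayers = as.integer(nLayers),
        spacing = c(s, s, dz), zOffset = transform@translation[3])
}

#' Test whether physical points fall inside one ROI cylinder
#'
#' Membership in the continuous cylinder (disk of `diameterPx` pixels around
#' the ROI centre, spanning its `nLayers` slices), evaluated for physical
#' scanner coordinates. Used to verify that rigidly propagated ROIs recover
#' the reference region.
#'
#' @param roiset a [RoiSet-class].
#' @param label material label.
#' @param pts n x 3 matrix of physical points (mm, scanner coordinates).
#' @param fov FOV (mm) of the protocol the ROI set was built on.
#' @return logical vector.
#' @export
roiRegionContains <- function(roiset, label, pts, fov) {
    r <- match(as.integer(label), roiset@materialLabels)
    if (is.na(r)) stop("unknown material label")
    s <- roiset@spacing[1]
    dz <- roiset@spacing[3]
    nz <- dim(roiset@labels)[3]
    ci <- roiset@centers[r, 1]
    cj <- roiset@centers[r, 2]
    kc <- roiset@centers[r, 3]
    pi <- (pts[, 1] + fov / 2) / s + 0.5
    pj <- (pts[, 2] + fov / 2) / s + 0.5
    inDisk <- (pi - ci)^2 + (pj - cj)^2 < (roiset@diameterPx / 2)^2
    kIdx <- kc + seq(-(roiset@nLayers - 1) %/% 2, roiset@nLayers %/% 2)
    zVals <- -nz * dz / 2 + (seq_len(nz) - 0.5) * dz + roiset@zOffset
    zlow <- zVals[min(kIdx)] - dz / 2
    zhigh <- zVals[max(kIdx)] + dz / 2
    inDisk & pts[, 3] >= zlow & pts[, 3] < zhigh
}
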