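#' @include AllClasses.R protocols.R utils.R
NULL

#' Default image-domain surrogate parameters for the scanner chain
#'
#' The scanner and reconstruction chain (spectral detection, 70 keV virtual
#' monochromatic synthesis, iterative denoising, kernels) is replaced by
#' declared image-domain surrogates so that every acquisition factor is
#' independently controllable:
#' \itemize{
#'   \item quantum noise SD `sigma_ref` (HU) at `ctdi_ref` mGy and
#'     `thickness_ref` mm, scaled by \eqn{\sqrt{CTDI_{ref}/CTDI}} and
#'     \eqn{\sqrt{t_{ref}/t}};
#'   \item a high-pitch noise multiplier `pitch_noise`;
#'   \item kernel point-spread FWHM in pixels and noise amplification per
#'     reconstruction kernel;
#'   \item a noise-SD reduction factor per QIR strength level;
#'   \item the repositioning rigid transform.
#' }
#'
#' @return named list of surrogate parameters.
#' @export
defaultPhysics <- function() {
    list(
        sigma_ref = 10, ctdi_ref = 10, thickness_ref = 1,
        pitch_noise = c(standard = 1, high_pitch = 1.15),
        kernel_fwhm_px = c(Qr40 = 1.2, Qr44 = 0.9, Qr48 = 0.7),
        kernel_noise_amp = c(Qr40 = 1, Qr44 = 1.35, Qr48 = 1.8),
        qir_noise_factor = c("0" = 1, "1" = 0.85, "2" = 0.7, "3" = 0.55,
                             "4" = 0.45),
        reposition = list(translation = c(3, -2, 1), rotationZ = 2))
}

#' Target noise SD of a protocol
#'
#' Quantum-noise scaling law of the simulator: the noise SD injected on the
#' protocol grid is
#' \deqn{\sigma = \sigma_{ref} \sqrt{CTDI_{ref}/CTDI}\;
#'   \sqrt{t_{ref}/t}\; m_{pitch}\, a_{kernel}\, f_{QIR}.}
#'
#' @param protocol one protocol row.
#' @param physics surrogate parameter list (default [defaultPhysics()]).
#' @return noise SD in HU.
#' @export
noiseSigma <- function(protocol, physics = defaultPhysics()) {
    physics$sigma_ref *
        sqrt(physics$ctdi_ref / protocol$ctdivol) *
        sqrt(physics$thickness_ref / protocol$slice_thickness) *
        physics$pitch_noise[[protocol$scan_mode]] *
        physics$kernel_noise_amp[[protocol$kernel]] *
        physics$qir_noise_factor[[as.character(protocol$qir_level)]]
}

# phantom -> scanner coordinates
applyTransform <- function(transform, pts) {
    th <- transform@rotationZ * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    xy <- pts[, 1:2, drop = FALSE] %*% t(R)
    cbind(xy[, 1] + transform@translation[1],
          xy[, 2] + transform@translation[2],
          pts[, 3] + transform@translation[3])
}

# scanner -> phantom coordinates
invertTransform <- function(transform, pts) {
    th <- -transform@rotationZ * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    xy <- cbind(pts[, 1] - transform@translation[1],
                pts[, 2] - transform@translation[2]) %*% t(R)
    cbind(xy[, 1], xy[, 2], pts[, 3] - transform@translation[3])
}

# Anti-alias a fine truth volume towards a protocol grid by integer block
# averaging (factors floor(target/fine) per axis).
blockAverageVolume <- function(truth, protocol) {
    sp <- truth@spacing
    target <- c(pixelSpacing(protocol), pixelSpacing(protocol),
                protocol$slice_thickness)
    if (any(target < sp - 1e-9))
        stop("resolution error: protocol grid (", paste(signif(target, 4),
             collapse = " x "), " mm) is finer than the truth grid (",
             paste(signif(sp, 4), collapse = " x "), " mm)")
    f <- pmax(1L, as.integer(floor(target / sp)))
    vals <- cppBlockMean3d(as.numeric(truth@values), dim(truth@values), f)
    # centre of block b sits at origin + ((b-1)*f + (f-1)/2) * sp
    volumeImage(array(vals, dim = dim(vals)), f * sp,
                truth@origin + (f - 1) / 2 * sp)
}

# z lattice of a protocol scan over a truth slab: slice count floor(ext/dz),
# centred on the (untransformed) truth centre.
protocolZGrid <- function(truth, protocol) {
    dz <- protocol$slice_thickness
    ext <- dim(truth@values)[3] * truth@spacing[3]
    nz <- max(1L, as.integer(floor(ext / dz)))
    cz <- truth@origin[3] + (dim(truth@values)[3] - 1) / 2 * truth@spacing[3]
    list(nz = nz, z = cz - nz * dz / 2 + (seq_len(nz) - 0.5) * dz)
}

# Core degradation chain operating on a pre-averaged truth: rigid transform,
# kVp contrast scaling, trilinear resampling onto the given scanner lattice,
# kernel PSF blur, correlated noise injection (QIR folded into the noise SD).
degradeAveraged <- function(avg, protocol, transform, seed, physics,
                            contrastFactor, xIdx, yIdx, zVals) {
    s <- pixelSpacing(protocol)
    fov <- protocol$fov
    xs <- -fov / 2 + (xIdx - 0.5) * s
    ys <- -fov / 2 + (yIdx - 0.5) * s
    d <- c(length(xs), length(ys), length(zVals))
    grid <- cbind(rep(xs, times = d[2] * d[3]),
                  rep(rep(ys, each = d[1]), times = d[3]),
                  rep(zVals, each = d[1] * d[2]))
    q <- invertTransform(transform, grid)
    vals <- cppTrilinear(as.numeric(avg@values), dim(avg@values),
                         avg@origin, avg@spacing, q)
    if (protocol$kvp == 140) vals <- vals * contrastFactor
    arr <- array(vals, dim = d)
    kxy <- gaussKernel(physics$kernel_fwhm_px[[protocol$kernel]] / 2.3548)
    if (length(kxy) > 1)
        arr <- array(cppSepConv3d(as.numeric(arr), d, kxy, kxy, 1, FALSE),
                     dim = d)
    sigma <- noiseSigma(protocol, physics)
    if (sigma > 0) {
        noise <- withSeed(seed, array(rnorm(prod(d)), dim = d))
        if (length(kxy) > 1) {
            noise <- cppSepConv3d(as.numeric(noise), d, kxy, kxy, 1, TRUE)
            noise <- noise / sqrt(sum(kxy^2)^2)
        }
        arr <- arr + sigma * array(noise, dim = d)
    }
    volumeImage(arr, c(s, s, protocol$slice_thickness),
                c(xs[1], ys[1], zVals[1]))
}

#' Simulate the acquisition of a truth volume under one protocol
#'
#' Applies, in order: the rigid repositioning transform; per-material contrast
#' scaling when the tube voltage is 140 kVp; anti-aliased resampling onto the
#' protocol grid (in-plane spacing `fov/matrix`, z spacing = slice thickness)
#' by block averaging followed by trilinear interpolation; the reconstruction
#' kernel point-spread blur; and correlated quantum noise whose SD follows
#' [noiseSigma()] (QIR denoising enters as its declared noise-SD reduction
#' factor). The output lattice is the scanner lattice: in-plane pixel centres
#' at \eqn{-FOV/2 + (i - 1/2)\,s}, slices centred on the truth slab. The same
#' (truth, protocol, transform, seed) always yields an identical volume.
#'
#' @param truth a fine-grid [VolumeImage-class] (whole phantom or one insert
#'   patch).
#' @param protocol one row of the protocol suite.
#' @param transform a [RigidTransform-class] (identity by default; the
#'   reposition protocol uses the configured transform).
#' @param seed integer seed for the noise realisation.
#' @param physics surrogate parameters, see [defaultPhysics()].
#' @param contrastFactor 140 kVp contrast multiplier of the imaged material.
#' @return a [VolumeImage-class] on the protocol grid covering the truth
#'   extent.
#' @export
simulateAcquisition <- function(truth, protocol, transform = rigidTransform(),
                                seed = 1L, physics = defaultPhysics(),
                                contrastFactor = 1) {
    stopifnot(is(truth, "VolumeImage"), is(transform, "RigidTransform"))
    avg <- blockAverageVolume(truth, protocol)
    s <- pixelSpacing(protocol)
    dmn <- dim(truth@values)
    ctr <- truth@origin + (dmn - 1) / 2 * truth@spacing
    tc <- applyTransform(transform, matrix(ctr, 1, 3))
    half <- (dmn[1:2] - 1) / 2 * truth@spacing[1:2]
    xi <- seq_len(protocol$matrix_size)
    xcen <- -protocol$fov / 2 + (xi - 0.5) * s
    xIdx <- xi[abs(xcen - tc[1]) <= half[1]]
    yIdx <- xi[abs(xcen - tc[2]) <= half[2]]
    if (!length(xIdx) || !length(yIdx))
        stop("geometry error: truth volume lies outside the protocol FOV")
    zg <- protocolZGrid(truth, protocol)
    degradeAveraged(avg, protocol, transform, seed, physics, contrastFactor,
                    xIdx, yIdx, zg$z + transform@translation[3])
}

#' Assemble a full protocol-grid volume of the whole phantom
#'
#' Pastes every degraded insert patch into a foam background on the complete
#' `matrix x matrix` scanner grid and overlays one correlated noise field.
#' Used for NIfTI export and inspection; the study pipeline extracts features
#' from the per-insert patches directly.
#'
#' @param truth a [PhantomGroundTruth-class].
#' @param protocol one protocol row.
#' @param transform rigid repositioning (identity by default).
#' @param seed integer seed.
#' @param physics surrogate parameters.
#' @return a [VolumeImage-class] of size matrix x matrix x slices.
#' @export
acquireProtocolVolume <- function(truth, protocol,
                                  transform = rigidTransform(), seed = 1L,
                                  physics = defaultPhysics()) {
    stopifnot(is(truth, "PhantomGroundTruth"))
    layout <- truth@layout
    s <- pixelSpacing(protocol)
    nxy <- protocol$matrix_size
    zg <- protocolZGrid(truth@patches[[1]], protocol)
    zVals <- zg$z + transform@translation[3]
    d <- c(nxy, nxy, zg$nz)
    out <- array(layout@backgroundHU, dim = d)
    xcen <- -protocol$fov / 2 + (seq_len(nxy) - 0.5) * s
    noNoise <- physics
    noNoise$sigma_ref <- 0
    for (r in seq_len(nrow(layout@materials))) {
        lab <- layout@materials$label[r]
        patch <- truth@patches[[as.character(lab)]]
        avg <- blockAverageVolume(patch, protocol)
        ctr <- patch@origin + (dim(patch@values) - 1) / 2 * patch@spacing
        tc <- applyTransform(transform, matrix(ctr, 1, 3))
        half <- (dim(patch@values)[1:2] - 1) / 2 * patch@spacing[1:2] - 1
        xIdx <- which(abs(xcen - tc[1]) <= half[1])
        yIdx <- which(abs(xcen - tc[2]) <= half[2])
        if (!length(xIdx) || !length(yIdx)) next
        cf <- layout@materials$kvp_factor[r]
        sim <- degradeAveraged(avg, protocol, transform, 0L, noNoise, cf,
                               xIdx, yIdx, zVals)
        out[xIdx, yIdx, ] <- sim@values
    }
    kxy <- gaussKernel(physics$kernel_fwhm_px[[protocol$kernel]] / 2.3548)
    sigma <- noiseSigma(protocol, physics)
    if (sigma > 0) {
        noise <- withSeed(deriveSeed(seed, 999), array(rnorm(prod(d)), dim = d))
        if (length(kxy) > 1) {
            noise <- cppSepConv3d(as.numeric(noise), d, kxy, kxy, 1, TRUE)
            noise <- noise / sqrt(sum(kxy^2)^2)
        }
        out <- out + sigma * array(noise, dim = d)
    }
    volumeImage(out, c(s, s, protocol$slice_thickness),
                c(xcen[1], xcen[1], zVals[1]))
}
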