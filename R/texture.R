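#' @include AllClasses.R utils.R
NULL

#' Generate a stationary random texture for one material
#'
#' Produces a seeded stationary random field with the requested marginal mean
#' and SD and a spatial autocorrelation scale set by the material's
#' correlation length. The texture family picks the generator:
#' \describe{
#'   \item{homogeneous}{white noise (correlation length ignored);}
#'   \item{granular}{Gaussian random field, isotropic Gaussian
#'     autocorrelation with scale `correlation_length`;}
#'   \item{fibrous}{anisotropic Gaussian field, correlation three times
#'     longer along z (the grain direction of the wood blocks);}
#'   \item{porous}{two-phase (binarised Gaussian) field emulating
#'     pore/matrix sponges.}
#' }
#' Fields are generated by circular convolution of white noise with a
#' normalized Gaussian kernel and rescaled analytically, so the marginal
#' variance is exact in expectation and the output is periodic (harmless
#' inside an insert patch).
#'
#' @param material one row of the material table (list or one-row data.frame
#'   with `family`, `mean_hu`, `texture_sd`, `correlation_length`).
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param seed integer seed; identical seeds give identical volumes.
#' @return a [VolumeImage-class] with the texture values.
#' @examples
#' mat <- materialTable()[3, ]
#' tex <- materialTexture(mat, c(32, 32, 32), 0.5, seed = 1)
#' @export
materialTexture <- function(material, shape, spacing, seed) {
    material <- as.list(material)
    shape <- as.integer(shape)
    if (length(shape) != 3L || any(shape < 1L)) stop("shape must be 3 positive integers")
    spacing <- rep(as.numeric(spacing), length.out = 3L)
    if (any(spacing <= 0)) stop("invalid geometry: spacing must be positive")
    if (material$texture_sd < 0) stop("texture_sd must be >= 0")
    n <- prod(shape)
    if (material$texture_sd == 0) {
        vals <- array(material$mean_hu, dim = shape)
        return(volumeImage(vals, spacing))
    }
    z <- withSeed(seed, array(rnorm(n), dim = shape))
    fam <- material$family
    if (fam == "homogeneous") {
        field <- z
    } else {
        cl <- material$correlation_length
        sig <- c(cl, cl, if (fam == "fibrous") 3 * cl else cl) / spacing
        bx <- boxesForSigma(sig[1]); by <- boxesForSigma(sig[2])
        bz <- boxesForSigma(sig[3])
        g <- cppBoxBlur3d(as.numeric(z), dim(z), bx, by, bz)
        # white noise filtered with a sum-1 separable kernel K has variance
        # sum(K^2) = prod over axes of the per-axis kernel sum of squares
        g <- g / sqrt(boxKernelSumSq(bx, shape[1]) *
                      boxKernelSumSq(by, shape[2]) *
                      boxKernelSumSq(bz, shape[3]))
        field <- array(g, dim = shape)
        if (fam == "porous") field <- ifelse(field > 0, 1, -1)
    }
    vals <- material$mean_hu + material$texture_sd * field
    volumeImage(vals, spacing)
}
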