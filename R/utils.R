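#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic mixing of a master seed and an integer salt, kept strictly
#' below 2^31 so the result is a valid R integer seed.
#'
#' @param master integer master seed.
#' @param salt integer salt identifying the consumer (stage, insert, protocol).
#' @return an integer seed.
#' @export
deriveSeed <- function(master, salt) {
    m <- as.numeric(master) %% 1000003
    s <- as.numeric(salt) %% 1000003
    as.integer((m * 20011 + s * 7919 + 104729) %% 2147483629)
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# Normalized Gaussian kernel truncated at +/- trunc sigma; length-1 kernel
# (identity) when sigma is effectively zero.
gaussKernel <- function(sigma, trunc = 2.5) {
    if (!is.finite(sigma) || sigma <= 1e-8) return(1)
    half <- max(1L, as.integer(ceiling(trunc * sigma)))
    x <- seq(-half, half)
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

# Odd widths of the three cascaded box filters approximating a Gaussian of
# the given sigma (in voxels); width 1 = identity.
boxesForSigma <- function(sigma, n = 3L) {
    if (!is.finite(sigma) || sigma <= 1e-8) return(rep(1L, n))
    wi <- sqrt(12 * sigma^2 / n + 1)
    wl <- floor(wi)
    if (wl %% 2 == 0) wl <- wl - 1
    wl <- max(1L, as.integer(wl))
    wu <- wl + 2L
    mi <- (12 * sigma^2 - n * wl^2 - 4 * n * wl - 3 * n) / (-4 * wl - 4)
    m <- max(0L, min(n, as.integer(round(mi))))
    c(rep(wl, m), rep(wu, n - m))
}

# Sum of squares of the effective (circularly wrapped to length len) kernel
# of a cascade of box filters; the white-noise variance after filtering.
boxKernelSumSq <- function(widths, len) {
    k <- 1
    for (w in widths) {
        if (w > 1) k <- convolve(c(k, numeric(w - 1)), rep(1 / w, w),
                                 type = "open")[seq_len(length(k) + w - 1)]
    }
    kw <- tapply(k, (seq_along(k) - 1) %% len, sum)
    sum(kw^2)
}

# log2 with 0 * log(0) = 0 convention for entropy sums
xlog2 <- function(p) {
    out <- numeric(length(p))
    pos <- p > 0
    out[pos] <- p[pos] * log2(p[pos])
    out
}

# Short content hash (FNV-1a over the serialized object) used for provenance.
settingsHash <- function(x) {
    bytes <- as.integer(serialize(x, NULL, version = 2))
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2147483647), b)
        h <- (h * 16777619) %% 2147483647
    }
    sprintf("%08x", as.integer(h))
}
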