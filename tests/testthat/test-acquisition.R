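makeTruthPatch <- function(sd = 0, mean = 0, n = 96, nz = 96, sp = 0.25,
                           seed = 1) {
    spec <- list(family = "homogeneous", mean_hu = mean, texture_sd = sd,
                 correlation_length = 1)
    materialTexture(spec, c(n, n, nz), sp, seed = seed)
}

test_that("acquisition is deterministic and lands on the protocol grid", {
    suite <- defaultProtocolSuite()
    ref <- getProtocol(suite, "reference")
    truth <- makeTruthPatch(sd = 50, mean = 100, seed = 2)
    a <- simulateAcquisition(truth, ref, seed = 9)
    b <- simulateAcquisition(truth, ref, seed = 9)
    expect_identical(volValues(a), volValues(b))
    expect_equal(volSpacing(a), c(400 / 512, 400 / 512, 1.0))

    s04 <- getProtocol(suite, "slice04")
    expect_equal(volSpacing(simulateAcquisition(truth, s04, seed = 1))[3], 0.4)

    hp <- getProtocol(suite, "high_pitch")
    expect_equal(volSpacing(simulateAcquisition(truth, hp, seed = 1))[1:2],
                 rep(350 / 512, 2))
})

test_that("a protocol grid finer than the truth grid is rejected", {
    coarse <- volumeImage(array(0, c(20, 20, 20)), c(1, 1, 1))
    s04 <- getProtocol(defaultProtocolSuite(), "slice04")
    expect_error(simulateAcquisition(coarse, s04, seed = 1),
                 "resolution error")
})

test_that("measured noise SD matches the declared noise law within 5%", {
    suite <- defaultProtocolSuite()
    ref <- getProtocol(suite, "reference")
    truth <- makeTruthPatch(sd = 0, mean = 0, n = 64, nz = 48)
    sds <- vapply(1:50, function(r) {
        sim <- simulateAcquisition(truth, ref, seed = 100 + r)
        sd(volValues(sim))
    }, numeric(1))
    expect_lt(abs(mean(sds) - noiseSigma(ref)) / noiseSigma(ref), 0.05)
})

test_that("the dose ladder scales noise as sqrt(CTDI_ref/CTDI)", {
    suite <- defaultProtocolSuite()
    ref <- getProtocol(suite, "reference")
    d05 <- getProtocol(suite, "dose05")
    truth <- makeTruthPatch(sd = 0, mean = 0, n = 64, nz = 32)
    sdRef <- sd(volValues(simulateAcquisition(truth, ref, seed = 7)))
    sdD05 <- sd(volValues(simulateAcquisition(truth, d05, seed = 7)))
    expect_lt(abs(sdD05 / sdRef - sqrt(10 / 0.47)) / sqrt(10 / 0.47), 0.10)
})

test_that("140 kVp applies the per-material contrast factor", {
    suite <- defaultProtocolSuite()
    kv <- getProtocol(suite, "kvp140")
    ref <- getProtocol(suite, "reference")
    truth <- makeTruthPatch(sd = 0, mean = 200, n = 64, nz = 32)
    nn <- defaultPhysics()
    nn$sigma_ref <- 0 # isolate the contrast step
    a <- simulateAcquisition(truth, kv, seed = 1, physics = nn,
                             contrastFactor = 1.03)
    b <- simulateAcquisition(truth, ref, seed = 1, physics = nn)
    expect_equal(volValues(a), volValues(b) * 1.03, tolerance = 1e-12)
})

test_that("repositioning recovers the same physical content", {
    # correlated texture: sub-voxel lattice offsets must not decorrelate it
    spec <- list(family = "granular", mean_hu = 0, texture_sd = 80,
                 correlation_length = 1.5)
    truth <- materialTexture(spec, c(128, 128, 96), 0.25, seed = 6)
    ref <- getProtocol(defaultProtocolSuite(), "reference")
    nn <- defaultPhysics()
    nn$sigma_ref <- 0
    tr <- rigidTransform(c(3, -2, 1), 0) # pure translation
    a <- simulateAcquisition(truth, ref, seed = 1, physics = nn)
    b <- simulateAcquisition(truth, ref, transform = tr, seed = 1,
                             physics = nn)
    # compare on the overlapping interior in physical coordinates
    av <- volValues(a)
    bv <- volValues(b)
    # b's lattice window is shifted with the phantom, so equal local indices
    # address (almost) the same physical content
    ia <- 8:(dim(av)[1] - 8)
    ja <- 8:(dim(av)[2] - 8)
    ka <- 8:(dim(av)[3] - 8)
    ccor <- cor(as.vector(av[ia, ja, ka]),
                as.vector(bv[ia, ja, ka]))
    expect_gt(ccor, 0.85) # same texture, sub-voxel interpolation differences
})

test_that("assembling the whole phantom volume covers the full matrix", {
    lay <- buildDefaultLayout(materials = materialTable()[c(3, 22), ],
                              slabThickness = 8)
    gt <- generateGroundTruth(lay, seed = 1)
    ref <- getProtocol(defaultProtocolSuite(), "reference")
    vol <- acquireProtocolVolume(gt, ref, seed = 3)
    expect_equal(dim(volValues(vol))[1:2], c(512L, 512L))
    expect_equal(volSpacing(vol), c(400 / 512, 400 / 512, 1))
    v <- volValues(vol)
    # foam background plus noise away from inserts
    corner <- v[1:40, 1:40, ]
    expect_lt(abs(mean(corner) - (-800)), 2)
    expect_lt(abs(sd(corner) - noiseSigma(ref)) / noiseSigma(ref), 0.15)
})
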