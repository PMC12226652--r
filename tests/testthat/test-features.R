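test_that("fixed-bin-width discretization follows the floor rule", {
    expect_equal(discretize(c(0, 24.9, 25, 50), 25)$levels, c(1L, 1L, 2L, 3L))
    d <- discretize(rep(7.3, 10), 25)
    expect_true(all(d$levels == 1L))
    expect_equal(d$ng, 1L)
    # the minimum always maps to level 1, for any offset
    for (off in c(-1000, 0, 12.5, 999)) {
        x <- c(off, off + 10, off + 80)
        expect_equal(discretize(x, 25)$levels[1], 1L)
    }
    expect_error(discretize(numeric(0), 25), "empty")
    expect_error(discretize(1:3, 0), "binWidth")
})

test_that("first-order features match their closed forms", {
    const <- firstOrderFeatures(rep(5, 100), voxelVolume = 2)
    expect_equal(const[["Mean"]], 5)
    expect_equal(const[["Variance"]], 0)
    expect_equal(const[["Uniformity"]], 1)
    expect_equal(const[["Entropy"]], 0)
    expect_equal(const[["Skewness"]], 0)
    expect_equal(const[["Kurtosis"]], 0)
    expect_true(all(attr(const, "degenerate")[c("Skewness", "Kurtosis")]))

    # equal counts in 4 distinct bins: Entropy 2 bits, Uniformity 1/4
    x <- rep(c(0, 30, 60, 90), each = 25)
    f <- firstOrderFeatures(x, voxelVolume = 1, binWidth = 25)
    expect_equal(f[["Entropy"]], 2)
    expect_equal(f[["Uniformity"]], 0.25)

    expect_length(firstOrderFeatures(rnorm(50), 1), 18L)
    expect_error(firstOrderFeatures(numeric(0), 1), "empty")

    # moment conventions: population denominator, kurtosis not excess
    y <- c(1, 2, 2, 3, 7)
    fy <- firstOrderFeatures(y, 1)
    expect_equal(fy[["Variance"]], mean((y - mean(y))^2))
    expect_equal(fy[["Kurtosis"]],
                 mean((y - mean(y))^4) / mean((y - mean(y))^2)^2)
    expect_equal(fy[["Energy"]], sum(y^2))
    expect_equal(fy[["TotalEnergy"]], sum(y^2) * 1)
    expect_equal(fy[["Percentile10"]], quantile(y, 0.1, names = FALSE))
})

test_that("the extractor emits exactly 93 features in the documented order", {
    set.seed(31)
    img <- volumeImage(array(rnorm(10 * 10 * 6, 100, 40), c(10, 10, 6)),
                       c(0.78, 0.78, 1))
    mask <- cylinderMask(c(10, 10, 6), 9, 2:5)
    fv <- extractFeatureVector(img, mask)
    expect_length(fv, 93L)
    expect_identical(names(fv), featureNames93())
    fam <- attr(fv, "family")
    expect_equal(as.vector(table(factor(fam, unique(fam)))),
                 c(18L, 24L, 16L, 16L, 14L, 5L))
    expect_false(any(grepl("shape", names(fv), ignore.case = TRUE)))
    # determinism
    expect_identical(as.numeric(fv),
                     as.numeric(extractFeatureVector(img, mask)))
    expect_error(extractFeatureVector(img, array(FALSE, c(10, 10, 6))),
                 "empty")
    expect_error(extractFeatureVector(img, mask[1:5, , ]), "geometry")
})

test_that("a constant ROI yields the declared degenerate values", {
    img <- volumeImage(array(7, c(6, 6, 6)), c(1, 1, 1))
    mask <- array(TRUE, c(6, 6, 6))
    fv <- extractFeatureVector(img, mask)
    expect_equal(fv[["glcm_JointEntropy"]], 0)
    expect_equal(fv[["glcm_MaximumProbability"]], 1)
    expect_equal(fv[["glcm_Correlation"]], 1)
    expect_equal(fv[["ngtdm_Contrast"]], 0)
    expect_equal(fv[["ngtdm_Busyness"]], 0)
    expect_equal(fv[["ngtdm_Coarseness"]], 1e6)
    expect_equal(fv[["firstorder_Skewness"]], 0)
    deg <- attr(fv, "degenerate")
    names(deg) <- names(fv)
    expect_true(deg[["glcm_Correlation"]])
    expect_true(deg[["ngtdm_Coarseness"]])
    expect_true(deg[["firstorder_Kurtosis"]])
})

test_that("discretized-texture features are invariant to a constant HU shift", {
    set.seed(77)
    arr <- array(rnorm(8 * 8 * 8, 0, 50), c(8, 8, 8))
    mask <- array(TRUE, c(8, 8, 8))
    f1 <- extractFeatureVector(volumeImage(arr, c(1, 1, 1)), mask)
    f2 <- extractFeatureVector(volumeImage(arr + 137, c(1, 1, 1)), mask)
    texture <- attr(f1, "family") != "firstorder"
    expect_equal(as.numeric(f1[texture]), as.numeric(f2[texture]),
                 tolerance = 1e-12)
    # shift-covariant first-order features move by exactly the shift
    expect_equal(f2[["firstorder_Mean"]], f1[["firstorder_Mean"]] + 137)
    expect_equal(f2[["firstorder_Entropy"]], f1[["firstorder_Entropy"]])
    expect_equal(f2[["firstorder_Variance"]], f1[["firstorder_Variance"]])
})

test_that("translating image and mask together leaves the vector unchanged", {
    set.seed(78)
    core <- array(rnorm(6 * 6 * 6, 0, 40), c(6, 6, 6))
    big1 <- array(-999, c(12, 12, 12))
    big2 <- array(-999, c(12, 12, 12))
    m1 <- array(FALSE, c(12, 12, 12))
    m2 <- array(FALSE, c(12, 12, 12))
    big1[2:7, 2:7, 2:7] <- core
    m1[2:7, 2:7, 2:7] <- TRUE
    big2[5:10, 6:11, 4:9] <- core
    m2[5:10, 6:11, 4:9] <- TRUE
    f1 <- extractFeatureVector(volumeImage(big1, c(1, 1, 1)), m1)
    f2 <- extractFeatureVector(volumeImage(big2, c(1, 1, 1)), m2)
    expect_equal(as.numeric(f1), as.numeric(f2), tolerance = 1e-12)
})

test_that("2D per-slice extraction also emits 93 features", {
    set.seed(79)
    img <- volumeImage(array(rnorm(9 * 9 * 4, 0, 30), c(9, 9, 4)),
                       c(1, 1, 1))
    mask <- array(TRUE, c(9, 9, 4))
    fv <- extractFeatureVector(img, mask,
        extractionSettings(dimensionality = "twoD_per_slice"))
    expect_length(fv, 93L)
    expect_true(all(is.finite(fv)))
})
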