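test_that("the default layout has 28 uniquely labelled inserts inside the FOV", {
    lay <- buildDefaultLayout()
    m <- layoutMaterials(lay)
    expect_equal(nrow(m), 28L)
    expect_equal(sort(m$label), 1:28)
    expect_equal(m$mean_hu[m$name == "water"], 0)
    cen <- insertCenters(lay)
    expect_true(all(sqrt(cen[, 1]^2 + cen[, 2]^2) + 16 <= 200))
    # deterministic
    expect_identical(buildDefaultLayout(), buildDefaultLayout())
    # kVp contrast factors within +/- 3 percent, exactly 1 for water
    expect_true(all(abs(m$kvp_factor - 1) <= 0.03 + 1e-9))
    expect_equal(m$kvp_factor[m$name == "water"], 1)
})

test_that("material textures have the requested moments and are seeded", {
    spec0 <- list(family = "homogeneous", mean_hu = 0, texture_sd = 0,
                  correlation_length = 1)
    tex0 <- materialTexture(spec0, c(8, 8, 8), 1, seed = 1)
    expect_true(all(volValues(tex0) == 0))

    spec <- list(family = "homogeneous", mean_hu = 300, texture_sd = 80,
                 correlation_length = 1)
    tex <- materialTexture(spec, c(64, 64, 64), 1, seed = 42)
    v <- volValues(tex)
    expect_lt(abs(mean(v) - 300), 4 * 80 / sqrt(64^3))
    expect_lt(abs(sd(v) - 80) / 80, 0.05)

    # determinism
    tex2 <- materialTexture(spec, c(64, 64, 64), 1, seed = 42)
    expect_identical(volValues(tex), volValues(tex2))

    expect_error(materialTexture(spec, c(8, 8, 8), -1, seed = 1),
                 "invalid geometry")
})

test_that("longer correlation length gives larger short-range autocorrelation", {
    lag1corr <- function(cl) {
        spec <- list(family = "granular", mean_hu = 0, texture_sd = 50,
                     correlation_length = cl)
        v <- volValues(materialTexture(spec, c(48, 48, 48), 0.5, seed = 5))
        # empirical autocorrelation at 1 mm (2 voxels) along x
        a <- v[1:46, , ]
        b <- v[3:48, , ]
        cor(as.vector(a), as.vector(b))
    }
    expect_gt(lag1corr(2.0), lag1corr(0.5))
})

test_that("the porous and fibrous families shape the field as declared", {
    po <- list(family = "porous", mean_hu = -700, texture_sd = 100,
               correlation_length = 2)
    v <- volValues(materialTexture(po, c(32, 32, 32), 0.5, seed = 3))
    expect_setequal(unique(as.vector(v)), c(-800, -600)) # two-phase
    fi <- list(family = "fibrous", mean_hu = -500, texture_sd = 60,
               correlation_length = 1)
    v <- volValues(materialTexture(fi, c(32, 32, 64), 0.5, seed = 4))
    alongZ <- cor(as.vector(v[, , 1:60]), as.vector(v[, , 5:64]))
    alongX <- cor(as.vector(v[1:28, , ]), as.vector(v[5:32, , ]))
    expect_gt(alongZ, alongX) # grain direction is z
})

test_that("ground truth is generated once per seed, labelled 1..28, water at 0 HU", {
    lay <- buildDefaultLayout()
    gt <- generateGroundTruth(lay, seed = 7)
    labs <- groundTruthLabels(gt, spacing = 2)
    expect_equal(sort(setdiff(unique(as.vector(volValues(labs))), 0L)), 1:28)

    gt2 <- generateGroundTruth(lay, seed = 7)
    expect_identical(gt@patches[["22"]]@values, gt2@patches[["22"]]@values)
    expect_identical(gt@patches[["5"]]@values, gt2@patches[["5"]]@values)

    # mean HU inside the water insert (texture SD 3, ~3M voxels)
    p22 <- gt@patches[["22"]]
    inside <- p22@values != lay@backgroundHU
    expect_lt(abs(mean(p22@values[inside])), 3)
})
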