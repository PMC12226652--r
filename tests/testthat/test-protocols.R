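test_that("the default suite reproduces the 13-protocol acquisition matrix", {
    suite <- defaultProtocolSuite()
    expect_equal(nrow(suite), 13L)
    expect_false(anyDuplicated(suite$id) > 0)

    ref <- getProtocol(suite, "reference")
    expect_equal(ref$kvp, 120)
    expect_equal(ref$mas, 127)
    expect_equal(ref$slice_thickness, 1.0)
    expect_equal(ref$matrix_size, 512L)
    expect_equal(ref$fov, 400)
    expect_equal(ref$rotation_time, 0.5)
    expect_equal(ref$pitch, 0.8)
    expect_equal(ref$ctdivol, 10.00)
    expect_equal(ref$qir_level, 4L)
    expect_equal(ref$kernel, "Qr40")

    hp <- getProtocol(suite, "high_pitch")
    expect_equal(hp$fov, 350)
    expect_equal(hp$pitch, 3.2)
    expect_equal(hp$rotation_time, 0.25)
    expect_equal(hp$scan_mode, "high_pitch")

    expect_equal(getProtocol(suite, "kvp140")$kvp, 140)
    expect_equal(getProtocol(suite, "kvp140")$mas, 87)
    expect_equal(getProtocol(suite, "slice04")$slice_thickness, 0.4)
    expect_equal(getProtocol(suite, "dose05")$ctdivol, 0.47)
    expect_equal(getProtocol(suite, "dose10")$ctdivol, 1.03)
    expect_equal(getProtocol(suite, "dose30")$ctdivol, 3.00)
    expect_equal(getProtocol(suite, "dose50")$ctdivol, 4.98)
    expect_equal(getProtocol(suite, "qir0")$qir_level, 0L)
    expect_equal(getProtocol(suite, "qir2")$qir_level, 2L)
    expect_equal(getProtocol(suite, "qr44")$kernel, "Qr44")
    expect_equal(getProtocol(suite, "qr48")$kernel, "Qr48")
})

test_that("protocol validation enforces the structural invariants", {
    suite <- defaultProtocolSuite()
    bad <- suite
    bad$fov[bad$id == "reference"] <- 350
    expect_error(validateProtocolSuite(bad), "high-pitch")
    bad <- suite
    bad$ctdivol[1] <- 0
    expect_error(validateProtocolSuite(bad), "ctdivol")
    expect_error(getProtocol(suite, "nope"), "unknown protocol")
})

test_that("noise law scales as the inverse square root of dose and thickness", {
    suite <- defaultProtocolSuite()
    s_ref <- noiseSigma(getProtocol(suite, "reference"))
    s_d05 <- noiseSigma(getProtocol(suite, "dose05"))
    expect_equal(s_d05 / s_ref, sqrt(10 / 0.47))
    s_sl <- noiseSigma(getProtocol(suite, "slice04"))
    expect_equal(s_sl / s_ref, sqrt(1 / 0.4))
    s_hp <- noiseSigma(getProtocol(suite, "high_pitch"))
    expect_equal(s_hp / s_ref, 1.15)
    s_q0 <- noiseSigma(getProtocol(suite, "qir0"))
    expect_equal(s_q0 / s_ref, 1 / 0.45)
    s_48 <- noiseSigma(getProtocol(suite, "qr48"))
    expect_equal(s_48 / s_ref, 1.8)
})
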