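test_that("ICC(A,1) matches the ANOVA mean-squares oracle", {
    # printed 4 x 2 toy design: columns differ by a constant offset
    x <- c(2, 4, 6, 8)
    m <- cbind(x, x + 1)
    got <- iccAbsoluteAgreement(m)

    # independent oracle: mean squares from aov()
    d <- data.frame(y = as.vector(m),
                    subj = factor(rep(1:4, 2)),
                    col = factor(rep(1:2, each = 4)))
    ms <- summary(stats::aov(y ~ subj + col, d))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    iccOracle <- (msr - mse) / (msr + (2 - 1) * mse + (2 / 4) * (msc - mse))
    expect_equal(got$icc, iccOracle, tolerance = 1e-12)
    expect_equal(got$ms_rows, msr, tolerance = 1e-12)
    expect_equal(got$ms_cols, msc, tolerance = 1e-12)
    expect_equal(got$ms_err, mse, tolerance = 1e-12)
    expect_lt(got$icc, 1)

    # identical columns with varying subjects: perfect agreement
    expect_equal(iccAbsoluteAgreement(cbind(x, x))$icc, 1)
    # all values identical: degenerate, defined as 1
    r <- iccAbsoluteAgreement(matrix(3, 4, 2))
    expect_true(r$degenerate)
    expect_equal(r$icc, 1)
    expect_error(iccAbsoluteAgreement(cbind(c(1, NA), c(1, 2))),
                 "non-finite")
})

test_that("ICC under the null is near zero and invariances hold", {
    set.seed(5150)
    m <- cbind(rnorm(1000), rnorm(1000))
    expect_lt(abs(iccAbsoluteAgreement(m)$icc), 0.1)

    set.seed(61)
    m2 <- matrix(rnorm(40), 10, 4)
    base <- iccAbsoluteAgreement(m2)$icc
    perm <- iccAbsoluteAgreement(m2[sample(10), ])$icc
    relab <- iccAbsoluteAgreement(m2[, sample(4)])$icc
    expect_equal(perm, base, tolerance = 1e-12)
    expect_equal(relab, base, tolerance = 1e-12)
})

test_that("Lin's CCC matches the closed form and its inequality", {
    x <- c(1, 2, 3)
    expect_equal(linCCC(x, c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
    expect_equal(as.numeric(linCCC(x, x)), 1)
    expect_lt(linCCC(x, c(3, 2, 1)), 0)
    expect_error(linCCC(1:3, 1:4), "length mismatch")
    cc <- linCCC(c(2, 2), c(2, 2))
    expect_equal(as.numeric(cc), 1)
    expect_true(attr(cc, "degenerate"))

    # |CCC| <= |Pearson r| on random pairs (Lin's inequality)
    set.seed(404)
    for (i in 1:1000) {
        n <- sample(3:20, 1)
        a <- rnorm(n)
        b <- rnorm(n) * runif(1, 0.5, 2) + runif(1, -2, 2) + 0.5 * a
        if (sd(a) == 0 || sd(b) == 0) next
        expect_lte(abs(linCCC(a, b)), abs(cor(a, b)) + 1e-12)
    }
})

test_that("reliability statistics degrade monotonically with added noise", {
    set.seed(321)
    x <- rnorm(40, 10, 4)
    sds <- c(0.1, 0.5, 2, 8)
    reps <- 200
    miccs <- sapply(sds, function(s) {
        mean(replicate(reps, {
            y <- x + rnorm(40, 0, s)
            iccAbsoluteAgreement(cbind(x, y))$icc
        }))
    })
    mcccs <- sapply(sds, function(s) {
        mean(replicate(reps, {
            y <- x + rnorm(40, 0, s)
            linCCC(x, y)
        }))
    })
    expect_true(all(diff(miccs) < 0))
    expect_true(all(diff(mcccs) < 0))
})

test_that("CV follows its two-point closed form and scale invariance", {
    expect_equal(coefficientOfVariation(rep(4, 5)), 0)
    expect_equal(coefficientOfVariation(c(9, 11)), 100 * sqrt(2) / 10,
                 tolerance = 1e-12)
    set.seed(8)
    x <- rnorm(20, 50, 5)
    expect_equal(coefficientOfVariation(3.7 * x), coefficientOfVariation(x),
                 tolerance = 1e-12)
    # NOT shift invariant
    expect_false(isTRUE(all.equal(coefficientOfVariation(x + 100),
                                  coefficientOfVariation(x))))
    expect_true(is.na(coefficientOfVariation(c(-1, 1))))
    expect_error(coefficientOfVariation(1), "at least 2")
})

test_that("QCD uses type-7 quantiles and flags the symmetric-zero case", {
    expect_equal(quartileCoefficientOfDispersion(1:5), 100 * 2 / 6,
                 tolerance = 1e-12)
    expect_equal(quartileCoefficientOfDispersion(rep(2, 4)), 0)
    expect_true(is.na(quartileCoefficientOfDispersion(c(-3, -1, 1, 3))))
    set.seed(9)
    x <- abs(rnorm(15, 10, 3))
    expect_equal(quartileCoefficientOfDispersion(2 * x),
                 quartileCoefficientOfDispersion(x), tolerance = 1e-12)
})

test_that("interpretation bins follow the declared edges", {
    expect_equal(classifyRobustness(0.95, "reliability"), "excellent")
    expect_equal(classifyRobustness(0.90, "reliability"), "excellent")
    expect_equal(classifyRobustness(0.89, "reliability"), "good")
    expect_equal(classifyRobustness(0.75, "reliability"), "good")
    expect_equal(classifyRobustness(0.50, "reliability"), "moderate")
    expect_equal(classifyRobustness(0.49, "reliability"), "poor")
    expect_equal(classifyRobustness(-0.2, "reliability"), "poor")

    expect_equal(classifyRobustness(15, "variability"), "moderate")
    expect_equal(classifyRobustness(10, "variability"), "moderate")
    expect_equal(classifyRobustness(9.99, "variability"), "acceptable")
    expect_equal(classifyRobustness(20, "variability"), "inadequate")
    expect_equal(classifyRobustness(NA_real_, "variability"), "undefined")
})
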