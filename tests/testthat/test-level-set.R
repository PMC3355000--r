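test_that("edge indicator: flat images, step edges and ramps", {
    # constant image: zero gradient everywhere -> g identically 1
    g <- edgeIndicator(matrix(3.7, 24, 24), sigma = 1.5)
    expect_true(all(g == 1))
    expect_true(all(g > 0 & g <= 1))

    # sharp step: minimum of g sits on the edge column
    step <- cbind(matrix(0, 32, 16), matrix(10, 32, 16))
    g2 <- edgeIndicator(step, sigma = 1)
    expect_true(min(which.min(colMeans(g2))) %in% 16:17)

    # linear ramp of slope a with no smoothing: g = 1 / (1 + a^2) exactly
    a <- 0.8
    ramp <- matrix(rep(a * seq_len(40), each = 20), 20, 40)
    g3 <- edgeIndicator(ramp, sigma = 0)
    expect_equal(unique(as.vector(round(g3[, 5:35], 12))), 1 / (1 + a^2))

    expect_error(edgeIndicator(matrix(c(1, NA, 1, 1), 2, 2), 1),
                 "finite")
})

test_that("level-set evolution: identity, fixed point and disk recovery", {
    img <- matrix(0, 48, 48)
    phi0 <- initialLevelSet(dim(img), "disk", center = c(24, 24), radius = 10)
    p0 <- levelSetParams(nIter = 0)
    expect_identical(as.vector(evolveLevelSet(img, phi0, p0)),
                     as.vector(phi0))

    # an exact signed distance field has (near) zero penalty energy and is a
    # fixed point of the pure-penalty flow up to discretization
    rows <- matrix(seq_len(48), 48, 48)
    cols <- matrix(seq_len(48), 48, 48, byrow = TRUE)
    sdf <- sqrt((rows - 24)^2 + (cols - 24)^2) - 10
    gradx <- (rbind(sdf[-1, ], sdf[48, ]) - rbind(sdf[1, ], sdf[-48, ])) / 2
    grady <- (cbind(sdf[, -1], sdf[, 48]) - cbind(sdf[, 1], sdf[, -48])) / 2
    penalty <- mean((sqrt(gradx^2 + grady^2) - 1)^2) / 2
    expect_lt(penalty, 1e-2)   # kink at the center dominates the residual
    pFix <- levelSetParams(lambdaLen = 1e-9, nuArea = 0, nIter = 50,
                           checkEvery = 1e9)
    phiF <- evolveLevelSet(img, sdf, pFix)
    # contour moves by at most sub-pixel jitter (< 5% of the disk area)
    expect_lt(sum((phiF < 0) != (sdf < 0)), 0.05 * pi * 100)

    # binary disk image, small seed inside, expansion: recovered contour
    # within 1 px Hausdorff distance of the true circle
    rows64 <- matrix(seq_len(64), 64, 64)
    cols64 <- matrix(seq_len(64), 64, 64, byrow = TRUE)
    disk <- matrix(0, 64, 64)
    disk[(rows64 - 32)^2 + (cols64 - 32)^2 <= 20^2] <- 100
    phi0 <- initialLevelSet(c(64, 64), "disk", center = c(32, 32), radius = 8)
    pExp <- levelSetParams(nuArea = -1.5, nIter = 800)
    phi <- evolveLevelSet(disk, phi0, pExp)
    mask <- extractZeroLevelRegion(phi)$mask
    rad <- sqrt((rows64 - 32)^2 + (cols64 - 32)^2)
    boundary <- mask & !(rbind(mask[-1, ], FALSE) & rbind(FALSE, mask[-64, ]) &
                         cbind(mask[, -1], FALSE) & cbind(FALSE, mask[, -64]))
    expect_lt(max(abs(rad[boundary] - 20)), 1 + sqrt(2) / 2)
})

test_that("divergent evolutions report the iteration index", {
    img <- matrix(rnorm(16 * 16), 16, 16)
    expect_error(evolveLevelSet(img, matrix(Inf, 16, 16),
                                levelSetParams(nIter = 5)),
                 "finite")
})

test_that("zero-level region extraction matches analytic area", {
    n <- 128
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    r <- 20.3
    phi <- sqrt((rows - 64.4)^2 + (cols - 64.6)^2) - r
    reg <- extractZeroLevelRegion(phi)
    expect_identical(reg$status, "ok")
    expect_lt(abs(sum(reg$mask) - pi * r^2) / (pi * r^2), 0.02)

    # single-sign fields are flagged
    regEmpty <- extractZeroLevelRegion(matrix(1, 8, 8))
    expect_identical(regEmpty$status, "no_interface")
    expect_identical(sum(regEmpty$mask), 0L)

    # sign flip gives the complementary mask
    regFlip <- extractZeroLevelRegion(-phi)
    expect_identical(regFlip$mask,
                     !reg$mask & phi != 0)  # complement minus the interface
})

test_that("stability constraint on the time step is enforced", {
    expect_error(levelSetParams(muPen = 0.3, tauStep = 1), "stability")
})
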