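test_that("step sampling follows the exponential free-path law", {
    expect_equal(sampleStep(0, 2), 0)
    expect_equal(sampleStep(1 - exp(-1), 1), 1)
    expect_error(sampleStep(0.5, 0), "muT")
    # empirical mean of many draws at mu_t = 2 is 0.5 mm
    set.seed(1)
    xi <- runif(1e6)
    s <- sampleStep(xi, 2)
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - 0.5), 3 * se)
})

test_that("Henyey-Greenstein sampling matches the phase function", {
    # isotropic limit: cos(theta) uniform on [-1, 1]
    cs0 <- hgDraws(1e5, 0, seed = 2)
    expect_true(all(cs0 >= -1 & cs0 <= 1))
    expect_lt(abs(mean(cs0)), 3 / sqrt(12 * 1e5) * 2)
    expect_lt(abs(mean(cs0 > 0) - 0.5), 0.01)
    # first moment equals g across anisotropies (tissue value included)
    for (g in c(0.5, 0.92, -0.5)) {
        cs <- hgDraws(1e6, g, seed = 3)
        se <- sd(cs) / sqrt(length(cs))
        expect_lt(abs(mean(cs) - g), 3 * se)
    }
    # chi-square goodness of fit against the closed-form CDF at g = 0.5
    cs <- hgDraws(1e6, 0.5, seed = 4)
    breaks <- seq(-1, 1, length.out = 41)
    obs <- table(cut(cs, breaks))
    pr <- diff(hgCdf(breaks, 0.5))
    expect_gt(stats::chisq.test(as.vector(obs), p = pr / sum(pr))$p.value,
              0.001)
})

test_that("scatter rotation preserves unit length and the polar angle", {
    res <- sampleScatter(c(0, 0, 1), 0.3, 0.7, 0.92)
    expect_equal(sqrt(sum(res$direction^2)), 1, tolerance = 1e-9)
    expect_equal(sum(res$direction * c(0, 0, 1)), res$cosTheta,
                 tolerance = 1e-9)
    oblique <- c(1, 2, 2) / 3
    res2 <- sampleScatter(oblique, 0.3, 0.7, 0.92)
    expect_equal(sum(res2$direction * oblique), res2$cosTheta,
                 tolerance = 1e-9)
    expect_error(sampleScatter(c(0, 0, 1), 0.1, 0.1, 1), "g")
})

test_that("absorption drops the packet-weight fraction mu_a / mu_t", {
    # scalp at 800 nm, reduced mode: 0.018 / (1.9 + 0.018)
    r <- absorbWeight(1, 0.018, 1.918)
    expect_equal(r$deltaW, 0.018 / 1.918, tolerance = 1e-12)
    expect_equal(r$weight, 1 - 0.018 / 1.918, tolerance = 1e-12)
    # non-absorbing medium
    r0 <- absorbWeight(0.5, 0, 2)
    expect_equal(r0$deltaW, 0)
    expect_equal(r0$weight, 0.5)
    # k successive interactions leave (1 - mu_a/mu_t)^k
    w <- 1
    for (i in 1:5) w <- absorbWeight(w, 0.3, 1.5)$weight
    expect_equal(w, (1 - 0.3 / 1.5)^5, tolerance = 1e-12)
    expect_error(absorbWeight(1, 0.1, 0), "muT")
})

test_that("Fresnel/Snell surface handling", {
    # normal incidence, tissue to air
    expect_equal(fresnelReflectance(1, 1.4, 1), (0.4 / 2.4)^2,
                 tolerance = 1e-12)
    # matched boundary: no reflection, direction unchanged
    expect_equal(fresnelReflectance(0.6, 1.33, 1.33), 0)
    out <- surfaceInteraction(c(0, 0, 1), c(0, 0, 1), 1.4, 1.4, xi = 0.99)
    expect_identical(out$type, "exit")
    expect_equal(out$direction, c(0, 0, 1))
    # 60 degrees from tissue (n = 1.4) exceeds the ~45.6 degree critical angle
    expect_identical(fresnelReflectance(cos(60 * pi / 180), 1.4, 1), 1)
    dir60 <- c(sin(60 * pi / 180), 0, cos(60 * pi / 180))
    tir <- surfaceInteraction(dir60, c(0, 0, 1), 1.4, 1, xi = 0.9999)
    expect_identical(tir$type, "reflect")
    expect_equal(tir$direction, c(dir60[1], 0, -dir60[3]))
    # refraction obeys Snell's law
    dir30 <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180))
    ex <- surfaceInteraction(dir30, c(0, 0, 1), 1.4, 1, xi = 0.9999)
    expect_identical(ex$type, "exit")
    sinOut <- sqrt(1 - sum(ex$direction * c(0, 0, 1))^2)
    expect_equal(sinOut, 1.4 * sin(30 * pi / 180), tolerance = 1e-9)
    expect_error(surfaceInteraction(dir30, c(0, 0, 2), 1.4, 1, 0.5),
                 "unit")
})

test_that("roulette is unbiased and leaves heavy packets alone", {
    r <- rouletteStep(0.5, 1e-4, 0.1, 0.99)
    expect_true(r$alive)
    expect_equal(r$weight, 0.5)
    rAlways <- rouletteStep(1e-6, 1e-4, 1, 0.5)
    expect_true(rAlways$alive)
    expect_equal(rAlways$weight, 1e-6)
    # expected post-roulette weight equals the pre-roulette weight
    set.seed(9)
    xi <- runif(2e4)
    w <- 5e-5
    post <- ifelse(xi < 0.1, w / 0.1, 0)
    se <- sd(post) / sqrt(length(post))
    expect_lt(abs(mean(post) - w), 3 * se)
    killed <- rouletteStep(5e-5, 1e-4, 0.1, 0.95)
    expect_false(killed$alive)
    expect_equal(killed$terminatedWeight, 5e-5)
})

test_that("free-path advance spends the budget voxel by voxel", {
    tab <- uniformTable(muA = 0.5, muSReduced = 1.5, g = 0, n = 1.4)
    lv <- homogeneousSlab(c(21, 21, 32))
    # homogeneous medium: the interaction lands exactly at budget / mu_t,
    # i.e. at the distance sample_step would give for the same draw
    xi <- 0.73
    budget <- -log(1 - xi)
    pkt <- photonPacket(c(10.5, 10.5, 1 + 1e-9), c(0, 0, 1))
    res <- advanceThroughVoxels(pkt, lv, tab, budget, 800)
    expect_identical(res$outcome, "interaction")
    travelled <- res$packet$position[3] - 1
    expect_equal(travelled, budget / 2, tolerance = 1e-7)
    expect_equal(travelled, sampleStep(xi, 2), tolerance = 1e-7)
    expect_equal(res$packet$timePs, travelled * 1.4 / 0.299792458,
                 tolerance = 1e-7)

    # two-layer path: budget B > mu_t1 d1 penetrates d1 + (B - mu_t1 d1)/mu_t2
    spec <- layeredSlabSpec(dims = c(21, 21, 32),
                            thicknesses = c(scalp = 5, skull = 0, csf = 0,
                                            gray = 0),
                            airBack = 1)
    lv2 <- makeLayeredSlabPhantom(spec)
    tb <- buildTissueTable()@table
    tb$mu_a_mm[] <- 0.2; tb$mu_s_reduced_mm[] <- 0.8   # mu_t = 1 everywhere
    tb$mu_a_mm[tb$code == 1] <- 1.0                    # scalp mu_t = 1.8
    tab2 <- methods::new("OpticalTable", table = tb)
    B <- 1.8 * 5 + 2.5    # spends 5 mm in scalp, then 2.5 mm deeper
    pkt2 <- photonPacket(c(10.5, 10.5, 1 + 1e-9), c(0, 0, 1))
    res2 <- advanceThroughVoxels(pkt2, lv2, tab2, B, 800)
    expect_identical(res2$outcome, "interaction")
    expect_equal(res2$packet$position[3] - 1, 5 + 2.5, tolerance = 1e-8)
    expect_equal(res2$packet$partialPath[1], 5, tolerance = 1e-8)

    # axis-aligned ray through k voxels accumulates exactly k mm of path
    pkt3 <- photonPacket(c(10.5, 10.5, 1 + 1e-9), c(0, 0, 1))
    res3 <- advanceThroughVoxels(pkt3, lv2, tab2, 1e9, 800)
    expect_identical(res3$outcome, "surface")
    expect_equal(sum(res3$packet$partialPath), 30, tolerance = 1e-6)
    expect_identical(res3$normal, c(0L, 0L, 1L))
    # visited mask covers scalp and white matter
    expect_equal(bitwAnd(res3$packet$visitedMask, as.integer(2^c(1, 5))),
                 as.integer(2^c(1, 5)))

    # escaping the bounding box without an air interface is an error
    noAir <- LabelVolume(array(5L, dim = c(5, 5, 5)))
    pkt4 <- photonPacket(c(2.5, 2.5, 2.5), c(0, 0, 1))
    expect_error(advanceThroughVoxels(pkt4, noAir, tab2, 1e9, 800),
                 "malformed")
})
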