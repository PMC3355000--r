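test_that("slab layer voxel counts equal thickness times face area", {
    spec <- layeredSlabSpec(dims = c(100, 100, 92),
                            thicknesses = c(scalp = 3, skull = 7, csf = 2,
                                            gray = 4),
                            airFront = 0)
    lv <- makeLayeredSlabPhantom(spec)
    counts <- tabulate(as.vector(tissueLabels(lv)) + 1L, nbins = 6L)
    expect_identical(counts[2], 3L * 100L * 100L)   # scalp
    expect_identical(counts[3], 7L * 100L * 100L)   # skull
    expect_identical(counts[4], 2L * 100L * 100L)   # csf
    expect_identical(counts[5], 4L * 100L * 100L)   # gray
    expect_identical(counts[6], (92L - 16L) * 100L * 100L)  # white fills
})

test_that("the default 92-slice model is 9.2 cm deep", {
    lv <- makeLayeredSlabPhantom(layeredSlabSpec(dims = c(16, 16, 92)))
    expect_equal(axialDepth(lv), 92)
    expect_equal(axialDepth(lv) / 10, 9.2)   # cm
    lv2 <- makeFoldedHeadPhantom(foldedHeadSpec(
        dims = c(64, 64, 92), semiAxes = c(24, 28, 92),
        thicknesses = c(scalp = 2, skull = 3, csf = 2, gray = 3),
        sulcusDepth = 4, fissureDepth = 6))
    expect_equal(axialDepth(lv2) / 10, 9.2)
})

test_that("degenerate slabs behave as documented", {
    allWhite <- makeLayeredSlabPhantom(layeredSlabSpec(
        dims = c(8, 8, 10),
        thicknesses = c(scalp = 0, skull = 0, csf = 0, gray = 0),
        airFront = 0))
    expect_true(all(tissueLabels(allWhite) == 5L))
    expect_error(makeLayeredSlabPhantom(layeredSlabSpec(
        dims = c(8, 8, 10),
        thicknesses = c(scalp = 5, skull = 5, csf = 2, gray = 2))),
        "exceed")
})

test_that("folded head: CSF monotone in expansion, no-op folds, watertight", {
    spec1 <- foldedHeadSpec(dims = c(72, 72, 30), semiAxes = c(30, 33, 40),
                            fissureDepth = 12)
    spec2 <- foldedHeadSpec(dims = c(72, 72, 30), semiAxes = c(30, 33, 40),
                            fissureDepth = 12, csfExpansion = 2)
    lv1 <- makeFoldedHeadPhantom(spec1)
    lv2 <- makeFoldedHeadPhantom(spec2)
    csf1 <- sum(tissueLabels(lv1) == 3L)
    csf2 <- sum(tissueLabels(lv2) == 3L)
    expect_gt(csf2, csf1)

    # zero sulci and zero-width fissure give plain concentric shells:
    # carving only ever turns cortex voxels into CSF
    spec0 <- foldedHeadSpec(dims = c(72, 72, 30), semiAxes = c(30, 33, 40),
                            fissureDepth = 12,
                            sulcusCount = 0, fissureWidth = 0)
    lv0 <- makeFoldedHeadPhantom(spec0)
    diffs <- tissueLabels(lv0) != tissueLabels(lv1)
    expect_true(all(tissueLabels(lv1)[diffs] == 3L))
    expect_true(all(tissueLabels(lv0)[diffs] >= 4L))

    # deterministic given spec
    expect_identical(tissueLabels(makeFoldedHeadPhantom(spec1)),
                     tissueLabels(lv1))

    # watertight: no air voxel inside the head (inside the skull shell)
    d <- dim(tissueLabels(lv1))
    ctr <- d / 2 * 1
    inner <- array(FALSE, d)
    for (zi in seq_len(d[3])) {
        x <- (seq_len(d[1]) - 0.5) - 36
        y <- (seq_len(d[2]) - 0.5) - 36
        z <- (zi - 0.5) - 30
        inner[, , zi] <- outer((x / 25)^2, (y / 28)^2, "+") + (z / 35)^2 <= 1
    }
    expect_true(all(tissueLabels(lv1)[inner] != 0L))
})

test_that("fold depth beyond the cortical extent is rejected", {
    expect_error(makeFoldedHeadPhantom(
        foldedHeadSpec(dims = c(64, 64, 30), semiAxes = c(24, 26, 30),
                       sulcusDepth = 20)),
        "exceeds")
})

test_that("synthetic MRI is seeded, reproducible and calibrated", {
    lv <- makeFoldedHeadPhantom(foldedHeadSpec(
        dims = c(64, 64, 20), semiAxes = c(26, 28, 30),
        sulcusDepth = 6, fissureDepth = 8))
    # noise-free limit: piecewise-constant image equal to class means
    img0 <- makeSyntheticMRI(lv, seed = 5)
    means <- c(air = 5, scalp = 90, skull = 30, csf = 15, gray = 60,
               white = 85)
    lab <- tissueLabels(lv)
    for (tn in names(means)) {
        code <- tissueCodes()[[tn]]
        if (any(lab == code))
            expect_true(all(intensities(img0)[lab == code] == means[[tn]]))
    }
    # determinism
    imgA <- makeSyntheticMRI(lv, classSds = snr10Sds(), seed = 11)
    imgB <- makeSyntheticMRI(lv, classSds = snr10Sds(), seed = 11)
    expect_identical(intensities(imgA), intensities(imgB))
    # law of large numbers: per-class sample means within 3 standard errors
    sds <- snr10Sds()
    big <- names(Filter(function(code) sum(lab == code) >= 1e4,
                        as.list(tissueCodes())))
    expect_gte(length(big), 2)
    for (tn in big) {
        code <- tissueCodes()[[tn]]
        nvox <- sum(lab == code)
        se <- sds[[tn]] / sqrt(nvox)
        expect_lt(abs(mean(intensities(imgA)[lab == code]) - means[[tn]]),
                  3 * se + 1e-12)
    }
    # missing class parameters are an error
    expect_error(makeSyntheticMRI(lv, classMeans = c(air = 0)), "missing")
})
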