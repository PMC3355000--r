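test_that("sensitivity profiles sum detected traversal, and are additive", {
    lv <- homogeneousSlab(c(41, 41, 22))
    lay <- buildSlabLayout(lv, separationsMm = c(6, 12), type = "ring",
                           ringWidthMm = 4)
    cfg <- simulationConfig(lv, lay, nPhotons = 500, seed = 2,
                            table = uniformTable(0.01, 1, g = 0, n = 1),
                            scatteringMode = "physical",
                            recordPaths = TRUE, sspDetectors = c(1, 2))
    res <- runSimulation(cfg)
    d <- detections(res)
    expect_gt(nrow(d), 10)

    # R-side accumulation over logs equals the kernel accumulator
    sspR <- sspAccumulate(res@paths, d, 1, gridDim(lv))
    expect_equal(sspR@values, res@ssp[["1"]], tolerance = 1e-10)

    # one detected photon: support is exactly its visited voxels
    one <- d[1, ]
    p1 <- Filter(function(p) p$photon == one$photon, res@paths)[[1]]
    ssp1 <- sspAccumulate(res@paths, one, one$detector, gridDim(lv))
    expect_setequal(which(ssp1@values > 0), unique(p1$voxel))

    # normalized profile sums to one
    sspN <- sspAccumulate(res@paths, d, 1, gridDim(lv), normalize = TRUE)
    expect_equal(sum(sspN@values), 1, tolerance = 1e-12)

    # additivity over disjoint photon subsets
    half <- d[d$detector == 1, ][seq_len(floor(sum(d$detector == 1) / 2)), ]
    rest <- d[d$detector == 1, ][-seq_len(nrow(half)), ]
    sspA <- sspAccumulate(res@paths, half, 1, gridDim(lv))
    sspB <- sspAccumulate(res@paths, rest, 1, gridDim(lv))
    expect_equal(sspA@values + sspB@values, sspR@values, tolerance = 1e-10)

    # a detector with no detections yields an empty, flagged profile
    empty <- sspAccumulate(res@paths, d[0, ], 2, gridDim(lv))
    expect_identical(empty@status, "empty")
    expect_true(all(empty@values == 0))
})

test_that("ballistic transmission lights up the source-detector line", {
    lv <- homogeneousSlab(c(21, 21, 12))
    lay <- buildSlabLayout(lv, separationsMm = numeric(0), type = "disk",
                           transmitted = TRUE, detRadiusMm = 2)
    cfg <- simulationConfig(lv, lay, nPhotons = 5, seed = 4,
                            table = uniformTable(0.01, 0, n = 1),
                            recordPaths = TRUE, maxTimePs = 5000)
    res <- runSimulation(cfg)
    ssp <- sspAccumulate(res@paths, detections(res), 1, gridDim(lv))
    hit <- which(ssp@values > 0, arr.ind = TRUE)
    expect_true(all(hit[, 1] == 11 & hit[, 2] == 11))  # central column only
    expect_identical(sort(unique(hit[, 3])), 2:11)     # every tissue slice
})

test_that("layer ratios partition detected weight by deepest visit", {
    lv <- makeLayeredSlabPhantom(layeredSlabSpec(
        dims = c(81, 81, 42),
        thicknesses = c(scalp = 3, skull = 7, csf = 2, gray = 4)))
    lay <- buildSlabLayout(lv, separationsMm = c(10, 20, 30), type = "ring",
                           ringWidthMm = 6)
    cfg <- simulationConfig(lv, lay, nPhotons = 3e4, seed = 6,
                            absorption = FALSE)
    res <- runSimulation(cfg)
    cur <- layerRatioCurves(res)
    defined <- cur[cur$defined, ]
    sums <- rowsum(defined$fraction, defined$separation_cm)
    expect_equal(as.vector(sums), rep(1, nrow(sums)), tolerance = 1e-12)

    # pathlength-based variant also partitions to one
    curP <- layerRatioCurves(res, method = "pathlength")
    definedP <- curP[curP$defined, ]
    sumsP <- rowsum(definedP$fraction, definedP$separation_cm)
    expect_equal(as.vector(sumsP), rep(1, nrow(sumsP)), tolerance = 1e-10)

    # a very thick scalp keeps shallow separations surface-dominated
    lvThick <- makeLayeredSlabPhantom(layeredSlabSpec(
        dims = c(81, 81, 62),
        thicknesses = c(scalp = 40, skull = 7, csf = 2, gray = 4)))
    layT <- buildSlabLayout(lvThick, separationsMm = 10, type = "ring",
                            ringWidthMm = 6)
    resT <- runSimulation(simulationConfig(lvThick, layT, nPhotons = 2e4,
                                           seed = 7, absorption = FALSE))
    curT <- layerRatioCurves(resT)
    surf <- curT$fraction[curT$group == "surface"]
    cort <- curT$fraction[curT$group == "cortex"]
    expect_gt(surf, cort)

    # packets that all visited white matter put the cortex ratio at 1
    det <- detections(res)
    deep <- det[bitwAnd(det$visited_mask, 32L) > 0, ]
    resDeep <- res
    resDeep@detections <- deep
    curD <- layerRatioCurves(resDeep)
    expect_true(all(curD$fraction[curD$defined & curD$group == "cortex"] == 1))
})

test_that("cross-point detection interpolates and flags edge cases", {
    # midpoint interpolation
    out <- findCrossSeparation(c(0.6, 0.4), c(0.4, 0.6), c(3, 4))
    expect_equal(out$separation_cm, 3.5)
    expect_identical(out$status, "ok")
    # crossing exactly on a grid point
    out2 <- findCrossSeparation(c(0.6, 0.5, 0.3), c(0.4, 0.5, 0.7), 1:3)
    expect_equal(out2$separation_cm, 2)
    # no crossing
    out3 <- findCrossSeparation(c(0.9, 0.8), c(0.1, 0.2), c(1, 2))
    expect_identical(out3$status, "none")
    expect_true(is.na(out3$separation_cm))
    # multiple crossings: smallest reported, multiplicity flagged
    out4 <- findCrossSeparation(c(0.6, 0.4, 0.6), c(0.4, 0.6, 0.4), 1:3)
    expect_identical(out4$status, "multiple")
    expect_equal(out4$separation_cm, 1.5)
    expect_identical(out4$nCrossings, 2L)
    # swapping the curves leaves the crossing where it was
    out5 <- findCrossSeparation(c(0.4, 0.6), c(0.6, 0.4), c(3, 4))
    expect_equal(out5$separation_cm, 3.5)
    expect_error(findCrossSeparation(c(1, 2), c(1, 2, 3), 1:3), "grid")
})

test_that("multi-wavelength runs derive seeds and respect absorption", {
    lv <- homogeneousSlab(c(61, 61, 31))
    lay <- buildSlabLayout(lv, separationsMm = c(5, 10, 15), type = "ring",
                           ringWidthMm = 4)
    # identical optical properties at two wavelengths + same seed stream
    # per wavelength index: curves identical when the table is flat
    tabFlat <- uniformTable(0.02, 1, g = 0.9, n = 1.4)
    cfg <- simulationConfig(lv, lay, nPhotons = 5000, seed = 9,
                            table = tabFlat, absorption = FALSE)
    mw <- runMultiwavelength(cfg, c(690, 780))
    i690 <- mw$intensity[mw$intensity$wavelength_nm == 690, "intensity"]
    i780 <- mw$intensity[mw$intensity$wavelength_nm == 780, "intensity"]
    cfg690 <- cfg; cfg690@wavelength <- 690
    cfg780b <- cfg; cfg780b@wavelength <- 780; cfg780b@seed <- cfg@seed
    expect_equal(i690,
                 intensityVsSeparation(runSimulation(cfg690))$intensity)
    expect_identical(
        detections(runSimulation(cfg780b))$weight,
        detections(runSimulation(cfg690))$weight)

    # raising absorption uniformly lowers detected intensity everywhere
    hi <- uniformTable(0.05, 1, g = 0.9, n = 1.4)
    cfgHi <- simulationConfig(lv, lay, nPhotons = 2e4, seed = 9, table = hi,
                              absorption = FALSE)
    cfgLo <- simulationConfig(lv, lay, nPhotons = 2e4, seed = 9,
                              table = uniformTable(0.01, 1, g = 0.9, n = 1.4),
                              absorption = FALSE)
    iHi <- intensityVsSeparation(runSimulation(cfgHi))
    iLo <- intensityVsSeparation(runSimulation(cfgLo))
    expect_true(all(iHi$intensity < iLo$intensity))

    expect_error(runMultiwavelength(cfg, c(690, 555)), "555")
})

test_that("deeper CSF expansion does not reduce cortical sampling", {
    mk <- function(f) makeFoldedHeadPhantom(foldedHeadSpec(
        dims = c(110, 110, 46), semiAxes = c(46, 50, 60),
        thicknesses = c(scalp = 3, skull = 7, csf = 2, gray = 4),
        csfExpansion = f, sulcusCount = 4, sulcusDepth = 8,
        fissureWidth = 3, fissureDepth = 15, centerFrac = 1))
    run <- function(lv) {
        lay <- buildProbeLayout(lv, separationsCm = c(2, 3),
                                sourceDepthMm = 25, detRadiusMm = 5)
        runSimulation(simulationConfig(lv, lay, nPhotons = 2e4, seed = 12,
                                       absorption = FALSE,
                                       recordPaths = TRUE,
                                       maxPathRecords = 8000))
    }
    # weighted mean of each detected packet's maximum penetration depth,
    # measured as distance inside the outer head ellipsoid
    depthStat <- function(res, lv) {
        d <- dim(tissueLabels(lv))
        ctr <- c(d[1] / 2, d[2] / 2, d[3])
        ax <- c(46, 50, 60)
        wOf <- stats::setNames(detections(res)$weight,
                               detections(res)$photon)
        depths <- vapply(res@paths, function(p) {
            vox <- p$voxel - 1L
            ix <- vox %% d[1]; rest <- vox %/% d[1]
            iy <- rest %% d[2]; iz <- rest %/% d[2]
            rhat <- sqrt(((ix + 0.5 - ctr[1]) / ax[1])^2 +
                         ((iy + 0.5 - ctr[2]) / ax[2])^2 +
                         ((iz + 0.5 - ctr[3]) / ax[3])^2)
            (1 - min(rhat)) * min(ax)
        }, numeric(1))
        w <- as.numeric(wOf[as.character(
            vapply(res@paths, `[[`, numeric(1), "photon"))])
        c(mean = sum(depths * w) / sum(w),
          se = sqrt(sum(w^2 * (depths - sum(depths * w) / sum(w))^2)) /
              sum(w))
    }
    lv1 <- mk(1); lv2 <- mk(2)
    s1 <- depthStat(run(lv1), lv1)
    s2 <- depthStat(run(lv2), lv2)
    expect_gt(s2[["mean"]],
              s1[["mean"]] - 3 * sqrt(s1[["se"]]^2 + s2[["se"]]^2))
})
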