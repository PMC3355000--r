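# shared fixtures and independent oracles

# homogeneous one-tissue slab (white matter fills everything between air pads)
homogeneousSlab <- function(dims = c(41, 41, 22), airBack = 1) {
    makeLayeredSlabPhantom(layeredSlabSpec(
        dims = dims,
        thicknesses = c(scalp = 0, skull = 0, csf = 0, gray = 0),
        airFront = 1, airBack = airBack))
}

# optical table with every tissue overridden to the same properties
uniformTable <- function(muA, muSReduced, g = 0, n = 1) {
    tb <- buildTissueTable()@table
    tb$mu_a_mm[] <- muA
    tb$mu_s_reduced_mm[] <- muSReduced
    tb$g[] <- g
    tb$n[] <- n
    methods::new("OpticalTable", table = tb)
}

# small folded-head phantom for segmentation tests (thicker layers so that
# per-class overlaps, not grid resolution, dominate the error)
segTestPhantom <- function() {
    foldedHeadSpec(dims = c(96, 96, 6), voxelSize = 1,
                   thicknesses = c(scalp = 5, skull = 6, csf = 4, gray = 6),
                   semiAxes = c(40, 44, 60), centerFrac = 0.5,
                   sulcusCount = 4, sulcusWidth = 2, sulcusDepth = 6,
                   fissureWidth = 3, fissureDepth = 12)
}

# per-class noise for an SNR-10 image (sd = mean / 10)
snr10Sds <- function() {
    c(air = 0.5, scalp = 9, skull = 3, csf = 1.5, gray = 6, white = 8.5)
}

dicePerClass <- function(truth, seg, classes = 1:5) {
    vapply(classes, function(k) {
        a <- tissueLabels(truth) == k
        b <- tissueLabels(seg) == k
        2 * sum(a & b) / (sum(a) + sum(b))
    }, numeric(1))
}

# independent flood-fill oracle: vectorized frontier expansion (repeated
# masked dilation by array shifts), seeds claimed in order
floodOracleR <- function(mask, seeds, connectivity) {
    d2 <- dim(mask)
    d <- if (length(d2) == 2L) c(d2, 1L) else d2
    m3 <- array(mask, dim = d)
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    mm <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
    offs <- offs[mm > 0 & mm <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ]
    shift <- function(a, dx, dy, dz) {
        out <- array(FALSE, dim = d)
        xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
        ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
        zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
        out[xs, ys, zs] <- a[xs - dx, ys - dy, zs - dz]
        out
    }
    lab <- array(0L, dim = d)
    for (s in seq_len(nrow(seeds))) {
        sd <- as.integer(seeds[s, ])
        if (length(sd) == 2L) sd <- c(sd, 1L)
        if (lab[sd[1], sd[2], sd[3]] != 0L) next
        reached <- array(FALSE, dim = d)
        reached[sd[1], sd[2], sd[3]] <- TRUE
        repeat {
            grown <- reached
            for (k in seq_len(nrow(offs)))
                grown <- grown | shift(reached, offs$dx[k], offs$dy[k],
                                       offs$dz[k])
            grown <- grown & m3 & lab == 0L
            if (all(grown == reached)) break
            reached <- grown
        }
        lab[reached] <- s
    }
    array(lab, dim = d2)
}

# closed-form Henyey-Greenstein CDF of cos(theta)
hgCdf <- function(x, g) {
    if (abs(g) < 1e-8) return((x + 1) / 2)
    (1 - g^2) / (2 * g) * (1 / sqrt(1 + g^2 - 2 * g * x) - 1 / (1 + g))
}

# time-domain diffusion reflectance from a semi-infinite medium
# (extrapolated-boundary image pair), up to a constant factor
diffusionReflectance <- function(t, rho, muA, muSp, n = 1) {
    v <- 0.299792458 / n
    D <- 1 / (3 * (muA + muSp))
    z0 <- 1 / muSp
    zb <- 2 * D
    t^(-2.5) * exp(-muA * v * t) *
        (z0 * exp(-(rho^2 + z0^2) / (4 * D * v * t)) +
         (z0 + 2 * zb) * exp(-(rho^2 + (z0 + 2 * zb)^2) / (4 * D * v * t)))
}

diffusionPeakTime <- function(rho, muA, muSp, n = 1) {
    stats::optimize(function(t) -diffusionReflectance(t, rho, muA, muSp, n),
                    c(1, 5000))$minimum
}

# weighted histogram peak of detected arrival times (lowess-smoothed)
arrivalPeak <- function(times, weights, binPs = 10) {
    h <- rowsum(weights, floor(times / binPs))
    tm <- (as.numeric(rownames(h)) + 0.5) * binPs
    sm <- stats::lowess(tm, h[, 1], f = 0.2)
    sm$x[which.max(sm$y)]
}
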