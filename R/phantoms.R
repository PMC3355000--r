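#' @include AllClasses.R volumes.R
NULL

#' Layered-slab phantom specification
#'
#' A planar five-layer medium: air padding, then scalp, skull, CSF and gray
#' matter stacked along the axial axis from the illuminated face, with white
#' matter filling the remainder of the grid. Layer thicknesses default to
#' the head-model values used throughout the package (scalp 3 mm, skull
#' 7 mm, CSF 2 mm, gray matter 4 mm).
#'
#' @param dims grid dimensions (voxels), default \code{c(256, 256, 92)}.
#' @param voxelSize voxel edge length(s) in mm.
#' @param thicknesses named numeric, mm of scalp, skull, csf, gray.
#' @param airFront axial air slices before the scalp (the illuminated face
#'   needs an air interface for launch and exit bookkeeping).
#' @param airBack axial air slices at the deep face (0 = white matter to the
#'   grid edge).
#' @return a \linkS4class{PhantomSpec}.
#' @export
layeredSlabSpec <- function(dims = c(256, 256, 92), voxelSize = 1,
                            thicknesses = c(scalp = 3, skull = 7, csf = 2,
                                            gray = 4),
                            airFront = 1, airBack = 0) {
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    need <- c("scalp", "skull", "csf", "gray")
    if (!all(need %in% names(thicknesses)))
        stop("thicknesses must name scalp, skull, csf and gray")
    methods::new("PhantomSpec", kind = "layered-slab",
                 dims = as.integer(dims), voxelSize = as.numeric(voxelSize),
                 thicknesses = thicknesses[need],
                 params = list(airFront = as.integer(airFront),
                               airBack = as.integer(airBack)))
}

#' Folded-head phantom specification
#'
#' Concentric ellipsoidal shells (scalp, skull, CSF, gray matter) around a
#' white-matter core, with CSF-filled sulcus grooves cut into the cortex and
#' a midline CSF-filled interhemispheric fissure. The half-ellipsoid sits on
#' the bottom grid face so that slice 1 is the head top, mirroring an MRI
#' acquisition covering the upper head. A CSF-expansion factor >= 1 scales
#' the CSF layer thickness, emulating an atrophic (expanded-CSF) brain.
#'
#' @param dims grid dimensions, default \code{c(256, 256, 92)} at 1 mm.
#' @param voxelSize voxel edge length(s) in mm.
#' @param thicknesses named numeric, mm of scalp, skull, csf, gray.
#' @param semiAxes ellipsoid semi-axes (mm) along x (left-right),
#'   y (anterior-posterior) and z (axial).
#' @param csfExpansion dimensionless factor >= 1 multiplying CSF thickness.
#' @param sulcusCount number of CSF-filled sulcus grooves (0 disables).
#' @param sulcusWidth groove width in mm.
#' @param sulcusDepth groove depth below the cortical surface in mm.
#' @param sulcusSpacing lateral spacing between grooves in mm.
#' @param fissureWidth midline fissure width in mm (0 disables).
#' @param fissureDepth midline fissure depth in mm.
#' @param centerFrac axial position of the ellipsoid center as a fraction of
#'   the grid depth (1 = bottom face, giving a top-half head).
#' @return a \linkS4class{PhantomSpec}.
#' @export
#' @examples
#' spec <- foldedHeadSpec(dims = c(64, 64, 24), semiAxes = c(24, 28, 40))
#' lv <- makeFoldedHeadPhantom(spec)
foldedHeadSpec <- function(dims = c(256, 256, 92), voxelSize = 1,
                           thicknesses = c(scalp = 3, skull = 7, csf = 2,
                                           gray = 4),
                           semiAxes = c(80, 100, 92),
                           csfExpansion = 1,
                           sulcusCount = 8, sulcusWidth = 2,
                           sulcusDepth = 10, sulcusSpacing = 14,
                           fissureWidth = 3, fissureDepth = 30,
                           centerFrac = 1) {
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    need <- c("scalp", "skull", "csf", "gray")
    if (!all(need %in% names(thicknesses)))
        stop("thicknesses must name scalp, skull, csf and gray")
    if (csfExpansion < 1)
        stop("csfExpansion must be >= 1")
    methods::new("PhantomSpec", kind = "folded-head",
                 dims = as.integer(dims), voxelSize = as.numeric(voxelSize),
                 thicknesses = thicknesses[need],
                 params = list(semiAxes = as.numeric(semiAxes),
                               csfExpansion = csfExpansion,
                               sulcusCount = as.integer(sulcusCount),
                               sulcusWidth = sulcusWidth,
                               sulcusDepth = sulcusDepth,
                               sulcusSpacing = sulcusSpacing,
                               fissureWidth = fissureWidth,
                               fissureDepth = fissureDepth,
                               centerFrac = centerFrac))
}

#' Build a layered-slab phantom
#'
#' @param spec a \linkS4class{PhantomSpec} from \code{\link{layeredSlabSpec}}.
#' @return a \linkS4class{LabelVolume}; each tissue layer occupies exactly
#'   thickness (in voxels) times the face area.
#' @export
makeLayeredSlabPhantom <- function(spec) {
    stopifnot(methods::is(spec, "PhantomSpec"), spec@kind == "layered-slab")
    d <- spec@dims; vz <- spec@voxelSize[3]
    th <- spec@thicknesses
    nvox <- th / vz
    if (any(abs(nvox - round(nvox)) > 1e-9))
        stop("layer thicknesses must be whole multiples of the axial voxel size")
    nvox <- as.integer(round(nvox))
    airF <- spec@params$airFront; airB <- spec@params$airBack
    total <- airF + sum(nvox) + airB
    if (total > d[3])
        stop(sprintf("layer thicknesses (%d slices incl. air) exceed grid depth (%d slices)",
                     total, d[3]))
    perSlice <- c(rep(0L, airF),
                  rep(1L, nvox[1]), rep(2L, nvox[2]),
                  rep(3L, nvox[3]), rep(4L, nvox[4]),
                  rep(5L, d[3] - total), rep(0L, airB))
    labels <- array(rep(perSlice, each = d[1] * d[2]), dim = d)
    LabelVolume(labels, spec@voxelSize)
}

#' Build the folded five-layer head phantom
#'
#' Deterministic construction: shells are nested ellipsoids obtained by
#' shrinking the outer semi-axes by the cumulative layer thicknesses, so the
#' model is watertight (no air inside the head). Sulcus grooves and the
#' interhemispheric fissure are carved out of the cortex and filled with CSF
#' (code 3).
#'
#' @param spec a \linkS4class{PhantomSpec} from \code{\link{foldedHeadSpec}}.
#' @return a \linkS4class{LabelVolume}.
#' @export
makeFoldedHeadPhantom <- function(spec) {
    stopifnot(methods::is(spec, "PhantomSpec"), spec@kind == "folded-head")
    d <- spec@dims; vs <- spec@voxelSize
    p <- spec@params
    th <- spec@thicknesses
    ax <- p$semiAxes
    f <- p$csfExpansion
    # cumulative inward offsets of the shell boundaries (mm)
    offs <- c(outer = 0,
              skullOut = th[["scalp"]],
              csfOut = th[["scalp"]] + th[["skull"]],
              grayOut = th[["scalp"]] + th[["skull"]] + th[["csf"]] * f,
              whiteOut = th[["scalp"]] + th[["skull"]] + th[["csf"]] * f +
                  th[["gray"]])
    cortexExtent <- min(ax) - offs[["grayOut"]]
    if (cortexExtent <= 0)
        stop("layer thicknesses exceed the smallest semi-axis")
    if (p$sulcusCount > 0 && p$sulcusDepth > cortexExtent)
        stop("sulcus depth exceeds the gray+white extent of the phantom")
    if (p$fissureWidth > 0 && p$fissureDepth > cortexExtent)
        stop("fissure depth exceeds the gray+white extent of the phantom")

    cx <- d[1] * vs[1] / 2
    cy <- d[2] * vs[2] / 2
    cz <- d[3] * vs[3] * p$centerFrac
    x <- (seq_len(d[1]) - 0.5) * vs[1] - cx
    y <- (seq_len(d[2]) - 0.5) * vs[2] - cy
    z <- (seq_len(d[3]) - 0.5) * vs[3] - cz

    labels <- array(0L, dim = d)
    insideSlice <- function(dOff, zi) {
        a <- ax - dOff
        if (any(a <= 0)) return(matrix(FALSE, d[1], d[2]))
        outer((x / a[1])^2, (y / a[2])^2, "+") + (z[zi] / a[3])^2 <= 1
    }
    codes <- c(1L, 2L, 3L, 4L, 5L)
    for (zi in seq_len(d[3])) {
        sl <- matrix(0L, d[1], d[2])
        for (k in seq_along(offs)) {
            m <- insideSlice(offs[k], zi)
            sl[m] <- codes[k]
        }
        labels[, , zi] <- sl
    }

    # carve CSF-filled folds: grooves reach from the cortical (gray) outer
    # surface down to sulcusDepth; the fissure runs along the midline plane.
    carve <- function(labels, halfWidth, depth, xcenters) {
        sel <- Reduce(`|`, lapply(xcenters, function(xc)
            abs(x + cx - xc) < halfWidth))
        if (!any(sel)) return(labels)
        for (zi in seq_len(d[3])) {
            outerM <- insideSlice(offs[["grayOut"]], zi)
            innerM <- insideSlice(offs[["grayOut"]] + depth, zi)
            band <- outerM & !innerM
            band[!sel, ] <- FALSE
            sl <- labels[, , zi]
            sl[band & sl >= 4L] <- 3L
            labels[, , zi] <- sl
        }
        labels
    }
    if (p$sulcusCount > 0 && p$sulcusWidth > 0) {
        half <- ceiling(p$sulcusCount / 2)
        offsets <- p$sulcusSpacing * seq_len(half)
        xc <- c(cx - offsets, cx + offsets)[seq_len(p$sulcusCount)]
        labels <- carve(labels, p$sulcusWidth / 2, p$sulcusDepth, xc)
    }
    if (p$fissureWidth > 0) {
        labels <- carve(labels, p$fissureWidth / 2, p$fissureDepth, cx)
    }
    LabelVolume(labels, vs)
}

#' Generate a synthetic T1-like MRI volume from a label volume
#'
#' Draws each voxel's intensity from a Gaussian whose mean and standard
#' deviation depend on its tissue code, emulating T1 contrast (CSF dark,
#' white matter and scalp fat bright) with additive Gaussian noise. Seeded
#' and reproducible; the global RNG state is untouched.
#'
#' @param lv a \linkS4class{LabelVolume}.
#' @param classMeans named numeric: mean intensity per tissue name (must
#'   cover every code present in \code{lv}).
#' @param classSds named numeric: per-tissue standard deviation (0 gives a
#'   piecewise-constant image).
#' @param seed RNG seed.
#' @return a \linkS4class{ScalarVolume} on the same grid.
#' @export
#' @examples
#' lv <- makeLayeredSlabPhantom(layeredSlabSpec(dims = c(8, 8, 12)))
#' img <- makeSyntheticMRI(lv, seed = 1)
makeSyntheticMRI <- function(lv,
                             classMeans = c(air = 5, scalp = 90, skull = 30,
                                            csf = 15, gray = 60, white = 85),
                             classSds = c(air = 0, scalp = 0, skull = 0,
                                          csf = 0, gray = 0, white = 0),
                             seed = 1) {
    stopifnot(methods::is(lv, "LabelVolume"))
    codes <- sort(unique(as.vector(lv@labels)))
    present <- tissueNames()[codes + 1L]
    if (!all(present %in% names(classMeans)))
        stop(sprintf("classMeans missing for tissue(s): %s",
                     paste(setdiff(present, names(classMeans)), collapse = ", ")))
    if (!all(present %in% names(classSds)))
        stop(sprintf("classSds missing for tissue(s): %s",
                     paste(setdiff(present, names(classSds)), collapse = ", ")))
    lab <- as.vector(lv@labels)
    mu <- as.numeric(classMeans[tissueNames()[lab + 1L]])
    sd <- as.numeric(classSds[tissueNames()[lab + 1L]])
    vals <- withLocalSeed(seed, mu + stats::rnorm(length(mu)) * sd)
    ScalarVolume(array(vals, dim = dim(lv@labels)), lv@voxelSize, lv@origin)
}
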