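#' @include AllClasses.R volumes.R
NULL

# ordered outer boundary of a head cross-section (points in mm, plane
# coordinates), sorted by angle around the section centroid
.orderedContour <- function(mask, spacing) {
    if (!any(mask)) return(NULL)
    nr <- nrow(mask); nc <- ncol(mask)
    pad <- matrix(FALSE, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- mask
    inner <- pad[2:(nr + 1), 2:(nc + 1)]
    nb <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
          pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
    boundary <- inner & !nb
    idx <- which(boundary, arr.ind = TRUE)
    pts <- cbind((idx[, 1] - 0.5) * spacing[1], (idx[, 2] - 0.5) * spacing[2])
    ctr <- colMeans(pts)
    ang <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1])
    pts[order(ang), , drop = FALSE]
}

# walk an ordered closed contour from the point nearest `from`, in the
# direction that initially increases coordinate `axis`, returning points at
# the requested arc lengths
.walkContour <- function(pts, from, arcLengths, axis = 1, increasing = TRUE) {
    n <- nrow(pts)
    d2 <- rowSums(sweep(pts, 2, from)^2)
    i0 <- which.min(d2)
    fwd <- pts[c(i0:n, 1:(i0 - 1)), , drop = FALSE]
    bwd <- pts[c(i0:1, n:(i0 + 1)), , drop = FALSE]
    pick <- function(path) {
        k <- min(10, nrow(path))
        mean(path[2:k, axis]) > path[1, axis]
    }
    path <- if (pick(fwd) == increasing) fwd else bwd
    seg <- sqrt(rowSums(diff(path)^2))
    cum <- c(0, cumsum(seg))
    out <- matrix(NA_real_, length(arcLengths), 2)
    for (i in seq_along(arcLengths)) {
        target <- arcLengths[i]
        if (target > max(cum)) next
        j <- findInterval(target, cum)
        j <- min(j, nrow(path) - 1)
        f <- (target - cum[j]) / max(cum[j + 1] - cum[j], 1e-12)
        out[i, ] <- path[j, ] + f * (path[j + 1, ] - path[j, ])
    }
    out
}

#' Build a surface probe layout on a head model
#'
#' Places the source on the frontal (anterior) surface of the head at a
#' given depth below the head top, pointing inward, and lays detectors
#' along the surface at the requested arc-length separations: along the
#' axial cross-section contour for the transverse arrangement, or along the
#' midsagittal contour (over the head top) for the sagittal arrangement.
#'
#' @param lv a \linkS4class{LabelVolume} head model.
#' @param separationsCm source-detector separations along the surface, cm.
#' @param view "transverse" or "sagittal".
#' @param sourceDepthMm depth of the source below the head top (slice
#'   axis), default 60 mm.
#' @param detRadiusMm detector aperture (disk) radius in mm.
#' @return a \linkS4class{ProbeLayout}; detectors whose arc length exceeds
#'   the available contour are dropped with a warning.
#' @export
buildProbeLayout <- function(lv, separationsCm = 1:10,
                             view = c("transverse", "sagittal"),
                             sourceDepthMm = 60, detRadiusMm = 1.5) {
    view <- match.arg(view)
    stopifnot(methods::is(lv, "LabelVolume"))
    lab <- lv@labels; vs <- lv@voxelSize; d <- dim(lab)
    zi <- min(max(1L, as.integer(ceiling(sourceDepthMm / vs[3]))), d[3])
    headZ <- lab[, , zi] > 0
    if (!any(headZ)) stop("no tissue at the requested source depth")
    # source: midline x, most anterior (smallest y) tissue voxel
    xs <- round(mean(range(which(rowSums(headZ) > 0))))
    ys <- which(headZ[xs, ])[1]
    srcVox <- c(xs, ys, zi)
    srcPos <- (srcVox - 0.5) * vs
    srcPos[2] <- (ys - 1) * vs[2] + 1e-6   # just inside the anterior face
    srcDir <- c(0, 1, 0)

    sepMm <- separationsCm * 10
    if (view == "transverse") {
        pts <- .orderedContour(headZ, vs[1:2])
        det2 <- .walkContour(pts, srcPos[1:2], sepMm, axis = 1)
        centers <- cbind(det2[, 1], det2[, 2], (zi - 0.5) * vs[3])
    } else {
        maskS <- lab[xs, , ] > 0    # (y, z) plane at the midline
        pts <- .orderedContour(maskS, vs[2:3])
        # walk toward the head top (decreasing z), continuing down the
        # posterior side once past the vertex
        det2 <- .walkContour(pts, c(srcPos[2], srcPos[3]), sepMm, axis = 2,
                             increasing = FALSE)
        centers <- cbind((xs - 0.5) * vs[1], det2[, 1], det2[, 2])
    }
    ok <- stats::complete.cases(centers)
    if (!all(ok))
        warning(sprintf("%d detector(s) beyond the available surface arc dropped",
                        sum(!ok)))
    methods::new("ProbeLayout", sourcePos = srcPos, sourceDir = srcDir,
                 detCenters = centers[ok, , drop = FALSE],
                 detRadius = detRadiusMm,
                 rings = matrix(numeric(0), 0, 2),
                 separationsCm = separationsCm[ok], view = view)
}

#' Build a slab probe layout
#'
#' Source at the center of the illuminated (top) face pointing down the
#' axial axis; detectors are either disks at the given lateral offsets or
#' concentric backscatter rings around the source (better statistics for
#' laterally homogeneous media).
#'
#' @param lv a \linkS4class{LabelVolume} slab (air above the first tissue
#'   slice).
#' @param separationsMm radial source-detector separations in mm.
#' @param type "ring" or "disk".
#' @param ringWidthMm ring width (mm) for type "ring".
#' @param detRadiusMm disk radius (mm) for type "disk".
#' @param transmitted if TRUE, adds one disk detector on the deep face
#'   opposite the source (separation entry 0 cm is appended).
#' @return a \linkS4class{ProbeLayout}.
#' @export
buildSlabLayout <- function(lv, separationsMm = seq(10, 30, 5),
                            type = c("ring", "disk"), ringWidthMm = 4,
                            detRadiusMm = 1.5, transmitted = FALSE) {
    type <- match.arg(type)
    stopifnot(methods::is(lv, "LabelVolume"))
    vs <- lv@voxelSize; d <- dim(lv@labels)
    ctr <- c(d[1] / 2 * vs[1], d[2] / 2 * vs[2])
    zcol <- lv@labels[ceiling(d[1] / 2), ceiling(d[2] / 2), ]
    zTop <- which(zcol > 0)[1]
    if (is.na(zTop)) stop("no tissue under the slab face center")
    srcPos <- c(ctr[1], ctr[2], (zTop - 1) * vs[3] + 1e-6)
    srcDir <- c(0, 0, 1)
    seps <- sort(separationsMm)
    if (type == "ring") {
        rings <- cbind(seps - ringWidthMm / 2, seps + ringWidthMm / 2)
        centers <- matrix(numeric(0), 0, 3)
        sepCm <- seps / 10
    } else {
        ang <- 0
        centers <- matrix(c(ctr[1] + seps * cos(ang),
                            ctr[2] + seps * sin(ang),
                            rep((zTop - 1) * vs[3], length(seps))),
                          ncol = 3)
        rings <- matrix(numeric(0), 0, 2)
        sepCm <- seps / 10
    }
    if (transmitted) {
        zBot <- max(which(zcol > 0))
        centers <- rbind(cbind(ctr[1], ctr[2], (zBot - 0.5) * vs[3]), centers)
        sepCm <- c(0, sepCm)
    }
    methods::new("ProbeLayout", sourcePos = srcPos, sourceDir = srcDir,
                 detCenters = centers, detRadius = detRadiusMm,
                 rings = rings, separationsCm = sepCm,
                 view = "slab")
}

setMethod("show", "ProbeLayout", function(object) {
    cat(sprintf("ProbeLayout (%s): source at (%.1f, %.1f, %.1f) mm, %d disk + %d ring detector(s)\n",
                object@view, object@sourcePos[1], object@sourcePos[2],
                object@sourcePos[3], nrow(object@detCenters),
                nrow(object@rings)))
    cat("  separations (cm):", paste(object@separationsCm, collapse = ", "),
        "\n")
    invisible(NULL)
})
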