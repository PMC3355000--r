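#' @include AllClasses.R simulate.R
NULL

.GROUPS <- c("surface", "csf", "cortex")

# deepest-layer-visited group from a visited-layer bit mask
.deepestGroup <- function(visited) {
    cortex <- bitwAnd(visited, bitwOr(bitwShiftL(1L, 4L),
                                      bitwShiftL(1L, 5L))) > 0L
    csf <- bitwAnd(visited, bitwShiftL(1L, 3L)) > 0L
    ifelse(cortex, "cortex", ifelse(csf, "csf", "surface"))
}

#' Accumulate a spatial sensitivity profile from traversal logs
#'
#' Sums each detected photon's per-voxel path length times its exit weight
#' into a volume: the map of where the light detected at one detector
#' traveled. Requires a run with \code{recordPaths = TRUE} (small runs);
#' for large runs request kernel-side accumulation via
#' \code{sspDetectors} in \code{\link{simulationConfig}}.
#'
#' @param paths list of per-photon logs (elements photon, voxel,
#'   length_mm), as in the \code{paths} slot of an \linkS4class{McResult}.
#' @param detections the detection data.frame.
#' @param detector detector index.
#' @param dims grid dimensions.
#' @param normalize scale to unit sum.
#' @return a \linkS4class{SensitivityVolume}; status "empty" (all-zero
#'   volume) when the detector saw no photons.
#' @export
sspAccumulate <- function(paths, detections, detector, dims,
                          normalize = FALSE) {
    vol <- array(0, dim = dims)
    sel <- detections[detections$detector == detector, , drop = FALSE]
    status <- if (nrow(sel) == 0) "empty" else "ok"
    if (nrow(sel) > 0) {
        wOf <- stats::setNames(sel$weight, sel$photon)
        for (p in paths) {
            key <- as.character(p$photon)
            if (!key %in% names(wOf)) next
            w <- wOf[[key]]
            acc <- rowsum(p$length_mm * w, p$voxel)
            vol[as.integer(rownames(acc))] <-
                vol[as.integer(rownames(acc))] + acc[, 1]
        }
        if (normalize && sum(vol) > 0) vol <- vol / sum(vol)
    }
    methods::new("SensitivityVolume", values = vol,
                 detector = as.integer(detector),
                 normalized = normalize, status = status)
}

#' Detected intensity versus source-detector separation
#'
#' Total detected packet weight per detector, ordered by separation.
#' Detectors with no detections keep a zero entry.
#'
#' @param result an \linkS4class{McResult} (or a detection data.frame with
#'   \code{layout} supplied).
#' @param layout the \linkS4class{ProbeLayout} (defaults to the one in
#'   \code{result}).
#' @return data.frame with separation_cm, intensity (summed weight),
#'   n (packet count), se (Monte Carlo standard error of the sum) and
#'   wavelength_nm.
#' @export
intensityVsSeparation <- function(result, layout = NULL) {
    if (methods::is(result, "McResult")) {
        det <- result@detections
        if (is.null(layout)) layout <- result@config@layout
        wl <- result@config@wavelength
    } else {
        det <- result
        if (is.null(layout)) stop("layout required with a raw data.frame")
        wl <- NA_real_
    }
    ndet <- length(layout@separationsCm)
    out <- data.frame(detector = seq_len(ndet),
                      separation_cm = layout@separationsCm,
                      intensity = 0, n = 0L, se = 0,
                      wavelength_nm = wl)
    if (nrow(det) > 0) {
        agg <- rowsum(det$weight, det$detector)
        agg2 <- rowsum(det$weight^2, det$detector)
        cnt <- rowsum(rep(1L, nrow(det)), det$detector)
        idx <- as.integer(rownames(agg))
        out$intensity[idx] <- agg[, 1]
        out$n[idx] <- cnt[, 1]
        out$se[idx] <- sqrt(agg2[, 1])
    }
    out
}

#' Layer-ratio curves: where did the detected light go?
#'
#' Partitions detected weight at each separation into mutually exclusive
#' groups by the deepest layer a packet visited: "surface" (scalp/skull
#' only), "csf" (reached CSF but not the brain) and "cortex" (reached gray
#' or white matter), and reports each group's weight fraction. Fractions
#' sum to 1 at every separation with detections; separations with zero
#' detected weight carry NA fractions and are flagged.
#'
#' @param result an \linkS4class{McResult}.
#' @param layout optional \linkS4class{ProbeLayout} override.
#' @param method "deepest" (default, weight partition by deepest visited
#'   layer) or "pathlength" (per-group partial-pathlength fraction of the
#'   total detected pathlength).
#' @return long data.frame: separation_cm, group, fraction, weight,
#'   defined, wavelength_nm.
#' @export
layerRatioCurves <- function(result, layout = NULL,
                             method = c("deepest", "pathlength")) {
    method <- match.arg(method)
    stopifnot(methods::is(result, "McResult"))
    det <- result@detections
    if (is.null(layout)) layout <- result@config@layout
    wl <- result@config@wavelength
    seps <- layout@separationsCm
    ndet <- length(seps)
    res <- expand.grid(detector = seq_len(ndet), group = .GROUPS,
                       stringsAsFactors = FALSE)
    res$separation_cm <- seps[res$detector]
    res$weight <- 0
    res$fraction <- NA_real_
    res$defined <- FALSE
    if (nrow(det) > 0) {
        if (method == "deepest") {
            grp <- .deepestGroup(det$visited_mask)
            w <- det$weight
        } else {
            pl <- cbind(surface = det$path_scalp + det$path_skull,
                        csf = det$path_csf,
                        cortex = det$path_gray + det$path_white)
            tot <- rowSums(pl)
            tot[tot == 0] <- 1
            # weight each packet's pathlength split by its exit weight
            grp <- rep(colnames(pl), each = nrow(det))
            w <- as.vector(pl / tot) * det$weight
            det <- det[rep(seq_len(nrow(det)), 3), ]
        }
        agg <- rowsum(w, paste(det$detector, grp, sep = ":"))
        keys <- do.call(rbind, strsplit(rownames(agg), ":"))
        for (i in seq_len(nrow(agg))) {
            di <- as.integer(keys[i, 1]); gi <- keys[i, 2]
            res$weight[res$detector == di & res$group == gi] <- agg[i, 1]
        }
    }
    totals <- rowsum(res$weight, res$detector)
    tot <- totals[as.character(res$detector), 1]
    ok <- tot > 0
    res$fraction[ok] <- res$weight[ok] / tot[ok]
    res$defined <- ok
    res$wavelength_nm <- wl
    res[order(res$detector, match(res$group, .GROUPS)),
        c("separation_cm", "group", "fraction", "weight", "defined",
          "wavelength_nm")]
}

#' Separation at which the cortex curve overtakes the surface curve
#'
#' Finds where (cortex - surface) changes sign along the separation grid,
#' linearly interpolating between adjacent grid points. With several
#' crossings the smallest separation is returned and the multiplicity
#' flagged; with none, the status says so.
#'
#' @param surface,cortex fraction values on a common separation grid (NA
#'   entries are dropped pairwise).
#' @param separations the separation grid (cm).
#' @return list(separation_cm, status = "ok"|"multiple"|"none",
#'   nCrossings).
#' @export
#' @examples
#' findCrossSeparation(c(0.6, 0.4), c(0.4, 0.6), c(3, 4))  # 3.5 cm
findCrossSeparation <- function(surface, cortex, separations) {
    if (length(surface) != length(cortex) ||
        length(surface) != length(separations))
        stop("curves must share one separation grid")
    keep <- is.finite(surface) & is.finite(cortex)
    surface <- surface[keep]; cortex <- cortex[keep]
    separations <- separations[keep]
    d <- cortex - surface
    hits <- numeric(0)
    for (i in seq_along(d)) {
        if (d[i] == 0) hits <- c(hits, separations[i])
        else if (i > 1 && sign(d[i]) != sign(d[i - 1]) && d[i - 1] != 0) {
            f <- d[i - 1] / (d[i - 1] - d[i])
            hits <- c(hits, separations[i - 1] +
                            f * (separations[i] - separations[i - 1]))
        }
    }
    hits <- sort(unique(hits))
    if (length(hits) == 0)
        list(separation_cm = NA_real_, status = "none", nCrossings = 0L)
    else
        list(separation_cm = hits[1],
             status = if (length(hits) > 1) "multiple" else "ok",
             nCrossings = length(hits))
}

#' Extract surface and cortex curves and locate their cross-point
#'
#' Convenience wrapper: computes layer-ratio curves and the interpolated
#' surface/cortex crossing separation.
#'
#' @param result an \linkS4class{McResult}.
#' @param ... passed to \code{\link{layerRatioCurves}}.
#' @return list(curves, cross) where cross is the
#'   \code{\link{findCrossSeparation}} result.
#' @export
crossPoint <- function(result, ...) {
    cur <- layerRatioCurves(result, ...)
    surf <- cur[cur$group == "surface", ]
    cort <- cur[cur$group == "cortex", ]
    cross <- findCrossSeparation(surf$fraction, cort$fraction,
                                 surf$separation_cm)
    list(curves = cur, cross = cross)
}

#' Run the simulation at several wavelengths
#'
#' Repeats one geometry at each wavelength with per-wavelength seeds
#' derived from the master seed, and collects intensity and layer-ratio
#' curves per wavelength.
#'
#' @param cfg a \linkS4class{SimulationConfig} (its wavelength is
#'   overridden per run).
#' @param wavelengths wavelengths (nm), all present in the table.
#' @return list with elements \code{results} (per-wavelength
#'   \linkS4class{McResult}), \code{intensity} and \code{ratios} (row-bound
#'   curve data.frames).
#' @export
runMultiwavelength <- function(cfg, wavelengths = c(690, 780, 830)) {
    stopifnot(methods::is(cfg, "SimulationConfig"))
    have <- unique(cfg@table@table$wavelength_nm)
    missing <- setdiff(wavelengths, have)
    if (length(missing))
        stop(sprintf("wavelength(s) %s missing from the optical table",
                     paste(missing, collapse = ", ")))
    out <- list()
    for (i in seq_along(wavelengths)) {
        wcfg <- cfg
        wcfg@wavelength <- wavelengths[i]
        wcfg@seed <- cfg@seed + 1000003 * (i - 1)
        out[[as.character(wavelengths[i])]] <- runSimulation(wcfg)
    }
    list(results = out,
         intensity = do.call(rbind, lapply(out, intensityVsSeparation)),
         ratios = do.call(rbind, lapply(out, layerRatioCurves)))
}

#' Write detection records as delimited text
#'
#' @param result an \linkS4class{McResult}.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeDetections <- function(result, path) {
    utils::write.table(result@detections, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Plot separation curves
#'
#' Base-graphics plots of log10 detected intensity versus separation and of
#' the layer-ratio curves.
#'
#' @param curves an intensity or ratio data.frame.
#' @param kind "intensity" or "ratio".
#' @param ... passed to \code{matplot}/\code{plot}.
#' @return invisibly NULL.
#' @export
plotSeparationCurves <- function(curves, kind = c("intensity", "ratio"),
                                 ...) {
    kind <- match.arg(kind)
    if (kind == "intensity") {
        ok <- curves$intensity > 0
        plot(curves$separation_cm[ok], log10(curves$intensity[ok]),
             type = "b", xlab = "source-detector separation (cm)",
             ylab = "log10 detected intensity", ...)
    } else {
        groups <- split(curves, curves$group)
        plot(NULL, xlim = range(curves$separation_cm), ylim = c(0, 1),
             xlab = "source-detector separation (cm)",
             ylab = "detected-weight fraction", ...)
        cols <- stats::setNames(c("firebrick", "steelblue", "darkgreen"),
                                .GROUPS)
        for (g in names(groups))
            graphics::lines(groups[[g]]$separation_cm,
                            groups[[g]]$fraction, type = "b",
                            col = cols[[g]], pch = 16)
        graphics::legend("topright", legend = names(groups),
                         col = cols[names(groups)], lty = 1, pch = 16)
    }
    invisible(NULL)
}
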