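#' @include AllClasses.R mc_ops.R probe_layout.R
NULL

#' Build a validated simulation configuration
#'
#' @param volume the \linkS4class{LabelVolume} head model.
#' @param layout the \linkS4class{ProbeLayout}; see
#'   \code{\link{buildProbeLayout}} / \code{\link{buildSlabLayout}}.
#' @param nPhotons number of photon packets to launch.
#' @param seed master RNG seed; every random stream derives from it, so an
#'   identical configuration reproduces results bit for bit.
#' @param wavelength source wavelength (nm), present in \code{table}.
#' @param table the \linkS4class{OpticalTable}
#'   (default \code{\link{buildTissueTable}()}).
#' @param scatteringMode "reduced" uses the tabulated reduced scattering
#'   coefficient directly as the scattering rate while sampling the
#'   anisotropic phase function; "physical" rescales to
#'   \code{mu_s = mu_s'/(1 - g)}.
#' @param maxTimePs time gate: packets exceeding this flight time are
#'   terminated to the ledger (default 1000 ps).
#' @param binWidthPs temporal bin width for time-binned outputs.
#' @param roulette list(on, threshold, survive); defaults on, 1e-4, 0.1.
#' @param boundary "open" terminates packets crossing the grid box to the
#'   ledger; "strict" raises an error (malformed volume).
#' @param absorption keep the per-voxel deposited-weight volume.
#' @param sspDetectors detector indices whose spatial sensitivity profile
#'   is accumulated (costs one double per voxel each).
#' @param recordPaths return per-photon sparse traversal logs for detected
#'   photons (small runs only).
#' @param maxPathRecords cap on recorded paths.
#' @param fluence accumulate the per-voxel, per-time-bin traversal weight
#'   of all photons (large memory; small grids only).
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(volume, layout, nPhotons, seed = 1,
                             wavelength = 800, table = buildTissueTable(),
                             scatteringMode = c("reduced", "physical"),
                             maxTimePs = 1000, binWidthPs = 1,
                             roulette = list(on = TRUE, threshold = 1e-4,
                                             survive = 0.1),
                             boundary = c("open", "strict"),
                             absorption = TRUE,
                             sspDetectors = integer(0),
                             recordPaths = FALSE, maxPathRecords = 10000,
                             fluence = FALSE) {
    scatteringMode <- match.arg(scatteringMode)
    boundary <- match.arg(boundary)
    roul <- utils::modifyList(list(on = TRUE, threshold = 1e-4,
                                   survive = 0.1), roulette)
    methods::new("SimulationConfig", volume = volume, table = table,
                 layout = layout, wavelength = wavelength,
                 nPhotons = as.numeric(nPhotons), seed = as.numeric(seed),
                 scatteringMode = scatteringMode, maxTimePs = maxTimePs,
                 binWidthPs = binWidthPs, roulette = roul,
                 boundary = boundary,
                 options = list(absorption = absorption,
                                sspDetectors = as.integer(sspDetectors),
                                recordPaths = recordPaths,
                                maxPathRecords = as.integer(maxPathRecords),
                                fluence = fluence))
}

# the launch voxel must be tissue adjacent to air (on the surface)
.checkOnSurface <- function(lab, vs, pos, what) {
    d <- dim(lab)
    vox <- pmin(pmax(floor(pos / vs) + 1, 1), d)
    if (lab[vox[1], vox[2], vox[3]] == 0)
        stop(sprintf("%s is not inside tissue", what))
    nearAir <- FALSE
    for (a in 1:3) for (s in c(-1L, 1L)) {
        nb <- vox; nb[a] <- nb[a] + s
        if (any(nb < 1) || any(nb > d)) { nearAir <- TRUE; next }
        if (lab[nb[1], nb[2], nb[3]] == 0L) nearAir <- TRUE
    }
    if (!nearAir)
        stop(sprintf("%s is not on the tissue surface", what))
    invisible(TRUE)
}

#' Run the time-resolved Monte Carlo simulation
#'
#' Launches photon packets at the source, alternates free-path advances
#' (optical-depth budget spent voxel by voxel) with combined
#' absorb-then-scatter interactions, applies Fresnel/Snell handling at the
#' air surface, records detected packets with their per-layer partial paths
#' and visited-layer mask, and closes a weight-conservation ledger.
#' Identical (seed, config) gives bit-identical output regardless of how
#' the run is partitioned, because every photon owns an RNG stream derived
#' from the master seed.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return an \linkS4class{McResult}.
#' @export
runSimulation <- function(cfg) {
    stopifnot(methods::is(cfg, "SimulationConfig"))
    lv <- cfg@volume
    lay <- cfg@layout
    mu <- .muVectors(cfg@table, cfg@wavelength, cfg@scatteringMode)
    .checkOnSurface(lv@labels, lv@voxelSize, lay@sourcePos, "source")
    if (nrow(lay@detCenters) > 0)
        for (i in seq_len(nrow(lay@detCenters)))
            .checkOnSurface(lv@labels, lv@voxelSize, lay@detCenters[i, ],
                            sprintf("detector %d", i))
    nBins <- as.integer(ceiling(cfg@maxTimePs / cfg@binWidthPs))
    disks <- if (nrow(lay@detCenters) > 0)
        cbind(lay@detCenters, lay@detRadius) else matrix(numeric(0), 0, 4)
    res <- cpp_run_mc(as.vector(lv@labels), dim(lv@labels), lv@voxelSize,
                      mu$muA, mu$muS, mu$g, mu$n,
                      lay@sourcePos, lay@sourceDir,
                      disks, lay@rings,
                      as.integer(cfg@nPhotons), cfg@seed,
                      cfg@maxTimePs, cfg@binWidthPs,
                      isTRUE(cfg@roulette$on), cfg@roulette$threshold,
                      cfg@roulette$survive,
                      cfg@boundary == "strict",
                      isTRUE(cfg@options$absorption),
                      cfg@options$sspDetectors,
                      isTRUE(cfg@options$recordPaths),
                      cfg@options$maxPathRecords,
                      isTRUE(cfg@options$fluence), nBins)
    d <- dim(lv@labels)
    absorb <- if (!is.null(res$absorption)) array(res$absorption, dim = d)
              else NULL
    ssp <- if (!is.null(res$ssp))
        lapply(res$ssp, function(v) array(v, dim = d)) else list()
    if (length(ssp)) names(ssp) <- as.character(cfg@options$sspDetectors)
    flu <- if (!is.null(res$fluence))
        array(res$fluence, dim = c(d, nBins)) else NULL
    paths <- if (!is.null(res$paths)) res$paths else list()
    methods::new("McResult", detections = res$detections,
                 ledger = res$ledger, absorption = absorb, ssp = ssp,
                 paths = paths, fluence = flu, config = cfg)
}

#' @rdname McResult-class
setMethod("detections", "McResult", function(x) x@detections)
#' @rdname McResult-class
setMethod("ledger", "McResult", function(x) x@ledger)

setMethod("show", "McResult", function(object) {
    led <- object@ledger
    cat(sprintf("McResult: %g photons at %g nm, %d detected\n",
                led[["launched"]], object@config@wavelength,
                as.integer(led[["n_detected"]])))
    bal <- led[["deposited"]] + led[["exited_detected"]] +
        led[["exited_undetected"]] + led[["roulette_killed"]] +
        led[["gate_terminated"]] + led[["escaped_bounds"]] +
        led[["safety_terminated"]]
    cat(sprintf("  ledger: deposited %.4g, exited %.4g, terminated %.4g (balance %.3g)\n",
                led[["deposited"]],
                led[["exited_detected"]] + led[["exited_undetected"]],
                led[["roulette_killed"]] + led[["gate_terminated"]] +
                led[["escaped_bounds"]],
                bal - led[["launched"]] - led[["roulette_gain"]]))
    invisible(NULL)
})

#' Weight-conservation audit of a run
#'
#' @param result an \linkS4class{McResult}.
#' @return relative imbalance |launched + roulette gain - accounted| /
#'   launched.
#' @export
conservationError <- function(result) {
    led <- result@ledger
    accounted <- led[["deposited"]] + led[["exited_detected"]] +
        led[["exited_undetected"]] + led[["roulette_killed"]] +
        led[["gate_terminated"]] + led[["escaped_bounds"]] +
        led[["safety_terminated"]]
    abs(accounted - led[["launched"]] - led[["roulette_gain"]]) /
        led[["launched"]]
}
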