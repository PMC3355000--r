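#' Tissue codes used throughout the package
#'
#' The five-layer head model uses integer voxel codes: 0 = air/background,
#' 1 = scalp, 2 = skull, 3 = cerebrospinal fluid (CSF), 4 = gray matter,
#' 5 = white matter.
#'
#' @return \code{tissueCodes} returns the named integer vector of codes;
#'   \code{tissueNames} the code-to-name lookup.
#' @export
#' @examples
#' tissueCodes()
tissueCodes <- function() {
    c(air = 0L, scalp = 1L, skull = 2L, csf = 3L, gray = 4L, white = 5L)
}

#' @rdname tissueCodes
#' @export
tissueNames <- function() {
    c("air", "scalp", "skull", "csf", "gray", "white")
}

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("arrayOrNULL", c("array", "NULL"))

#' Five-layer voxel head model
#'
#' A 3-D grid of tissue codes (see \code{\link{tissueCodes}}) with a physical
#' voxel size and origin. The axial (third) axis is the slice axis with slice
#' 1 at the head top; voxel \code{i} (1-based in R) spans the half-open
#' physical interval \code{[i-1, i) * voxelSize} along each axis.
#'
#' @slot labels integer 3-D array of tissue codes in 0..5.
#' @slot voxelSize numeric(3), physical edge lengths in mm.
#' @slot origin numeric(3), physical position (mm) of the corner of the
#'   first voxel.
#' @export
setClass("LabelVolume",
    representation(labels = "array", voxelSize = "numeric", origin = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@labels)) != 3L)
            msg <- c(msg, "labels must be a 3-D array")
        if (!is.integer(object@labels))
            msg <- c(msg, "labels must be integer")
        bad <- setdiff(unique(as.vector(object@labels)), 0:5)
        if (length(bad))
            msg <- c(msg, sprintf("unknown tissue code(s): %s",
                                  paste(bad, collapse = ", ")))
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 strictly positive numbers")
        if (length(object@origin) != 3L || any(!is.finite(object@origin)))
            msg <- c(msg, "origin must be 3 finite numbers")
        if (is.null(msg)) TRUE else msg
    })

#' T1-like intensity volume
#'
#' A 3-D grid of real intensities (arbitrary units) sharing the grid
#' conventions of \linkS4class{LabelVolume}.
#'
#' @slot intensities numeric 3-D array.
#' @slot voxelSize numeric(3) in mm.
#' @slot origin numeric(3) in mm.
#' @export
setClass("ScalarVolume",
    representation(intensities = "array", voxelSize = "numeric",
                   origin = "numeric"),
    validity = function(object) {
        msg <- NULL
        if (length(dim(object@intensities)) != 3L)
            msg <- c(msg, "intensities must be a 3-D array")
        if (any(!is.finite(object@intensities)))
            msg <- c(msg, "intensities must be finite")
        if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be 3 strictly positive numbers")
        if (is.null(msg)) TRUE else msg
    })

#' Per-tissue, per-wavelength optical properties
#'
#' Maps (tissue code, wavelength in nm) to absorption coefficient
#' \code{mu_a_mm} (mm^-1), reduced scattering coefficient
#' \code{mu_s_reduced_mm} (mm^-1), Henyey-Greenstein anisotropy \code{g} and
#' refractive index \code{n}. Built by \code{\link{buildTissueTable}}.
#'
#' @slot table data.frame with columns tissue, code, wavelength_nm, mu_a_mm,
#'   mu_s_reduced_mm, g, n.
#' @export
setClass("OpticalTable",
    representation(table = "data.frame"),
    validity = function(object) {
        need <- c("tissue", "code", "wavelength_nm", "mu_a_mm",
                  "mu_s_reduced_mm", "g", "n")
        msg <- NULL
        if (!all(need %in% names(object@table)))
            msg <- c(msg, "missing columns in optical table")
        else {
            tb <- object@table
            if (any(tb$mu_a_mm < 0) || any(tb$mu_s_reduced_mm < 0))
                msg <- c(msg, "mu_a and mu_s' must be non-negative")
            if (any(tb$g <= -1 | tb$g >= 1))
                msg <- c(msg, "anisotropy g must lie in (-1, 1)")
            if (any(tb$n < 1))
                msg <- c(msg, "refractive index must be >= 1")
            for (wl in unique(tb$wavelength_nm))
                if (!all(1:5 %in% tb$code[tb$wavelength_nm == wl]))
                    msg <- c(msg, sprintf(
                        "tissues 1-5 must all have entries at %g nm", wl))
        }
        if (is.null(msg)) TRUE else msg
    })

#' Phantom geometry specification
#'
#' Describes either a layered slab (planar five-layer medium, layers stacked
#' along the axial axis from the illuminated face) or a folded head
#' (concentric ellipsoidal shells with CSF-filled sulci and a midline
#' interhemispheric fissure). Constructed by \code{\link{layeredSlabSpec}} or
#' \code{\link{foldedHeadSpec}}.
#'
#' @slot kind "layered-slab" or "folded-head".
#' @slot dims integer(3) grid dimensions.
#' @slot voxelSize numeric(3) mm.
#' @slot thicknesses named numeric: scalp, skull, csf, gray thickness in mm.
#' @slot params list of geometry parameters (see constructors).
#' @export
setClass("PhantomSpec",
    representation(kind = "character", dims = "integer",
                   voxelSize = "numeric", thicknesses = "numeric",
                   params = "list"),
    validity = function(object) {
        msg <- NULL
        if (!object@kind %in% c("layered-slab", "folded-head"))
            msg <- c(msg, "kind must be 'layered-slab' or 'folded-head'")
        if (any(object@thicknesses < 0))
            msg <- c(msg, "layer thicknesses must be >= 0")
        if (length(object@dims) != 3L || any(object@dims < 1))
            msg <- c(msg, "dims must be 3 positive integers")
        if (any(object@voxelSize <= 0))
            msg <- c(msg, "voxelSize must be strictly positive")
        if (is.null(msg)) TRUE else msg
    })

#' Source-detector probe layout
#'
#' Source position/direction and detector geometry on the head (or slab)
#' surface. Disk detectors are flush circular apertures accepting all exit
#' angles; ring detectors (slabs only) are concentric annuli around the
#' source on the illuminated face.
#'
#' @slot sourcePos numeric(3) mm, launch position just inside tissue.
#' @slot sourceDir numeric(3), inward unit direction.
#' @slot detCenters k x 3 matrix of disk detector centers (mm).
#' @slot detRadius numeric, disk radius in mm.
#' @slot rings m x 2 matrix of annulus inner/outer radii (mm), may be empty.
#' @slot separationsCm numeric, nominal source-detector separations (cm),
#'   one per detector (disks then rings).
#' @slot view character, "transverse", "sagittal" or "slab".
#' @export
setClass("ProbeLayout",
    representation(sourcePos = "numeric", sourceDir = "numeric",
                   detCenters = "matrix", detRadius = "numeric",
                   rings = "matrix", separationsCm = "numeric",
                   view = "character"),
    validity = function(object) {
        msg <- NULL
        if (abs(sqrt(sum(object@sourceDir^2)) - 1) > 1e-6)
            msg <- c(msg, "sourceDir must be a unit vector")
        ndet <- nrow(object@detCenters) + nrow(object@rings)
        if (length(object@separationsCm) != ndet)
            msg <- c(msg, "need one separation per detector")
        if (is.unsorted(object@separationsCm))
            msg <- c(msg, "separations must be non-decreasing")
        if (is.null(msg)) TRUE else msg
    })

#' Monte Carlo simulation configuration
#'
#' Validated bundle of everything one run needs: head model, optical table,
#' wavelength, probe layout, photon count, seed, time gating, scattering
#' mode and roulette settings. Build with \code{\link{simulationConfig}}.
#'
#' @slot volume the \linkS4class{LabelVolume}.
#' @slot table the \linkS4class{OpticalTable}.
#' @slot layout the \linkS4class{ProbeLayout}.
#' @slot wavelength nm.
#' @slot nPhotons number of photon packets.
#' @slot seed master RNG seed (integer-valued).
#' @slot scatteringMode "reduced" (mu_s' used directly as the scattering
#'   rate) or "physical" (mu_s = mu_s'/(1-g)).
#' @slot maxTimePs time gate in ps.
#' @slot binWidthPs width of temporal bins in ps.
#' @slot roulette list(on, threshold, survive).
#' @slot boundary "open" (packets crossing the grid box are terminated to
#'   the ledger) or "strict" (error: malformed volume).
#' @slot options list of output switches (absorption, sspDetectors,
#'   recordPaths, maxPathRecords, fluence, nTimeBins).
#' @export
setClass("SimulationConfig",
    representation(volume = "LabelVolume", table = "OpticalTable",
                   layout = "ProbeLayout", wavelength = "numeric",
                   nPhotons = "numeric", seed = "numeric",
                   scatteringMode = "character", maxTimePs = "numeric",
                   binWidthPs = "numeric", roulette = "list",
                   boundary = "character", options = "list"),
    validity = function(object) {
        msg <- NULL
        if (object@nPhotons < 1) msg <- c(msg, "nPhotons must be >= 1")
        if (object@binWidthPs <= 0) msg <- c(msg, "binWidthPs must be > 0")
        if (object@maxTimePs < object@binWidthPs)
            msg <- c(msg, "maxTimePs must be >= binWidthPs")
        if (!object@scatteringMode %in% c("reduced", "physical"))
            msg <- c(msg, "scatteringMode must be 'reduced' or 'physical'")
        if (!object@boundary %in% c("open", "strict"))
            msg <- c(msg, "boundary must be 'open' or 'strict'")
        if (!object@wavelength %in% object@table@table$wavelength_nm)
            msg <- c(msg, sprintf("wavelength %g nm not present in table",
                                  object@wavelength))
        if (is.null(msg)) TRUE else msg
    })

#' Monte Carlo run result
#'
#' @slot detections data.frame of detected packets: photon, detector,
#'   weight, time_ps, per-tissue partial paths (mm), visited_mask.
#' @slot ledger named numeric conservation ledger (launched, deposited,
#'   exited, roulette, gate, escaped weights).
#' @slot absorption deposited-weight volume, or NULL.
#' @slot ssp list of per-detector sensitivity arrays (detected-photon
#'   traversal weight), possibly empty.
#' @slot paths list of per-photon sparse traversal logs (when recorded).
#' @slot fluence per-voxel, per-time-bin traversal weight array, or NULL.
#' @slot config the \linkS4class{SimulationConfig} that produced the run.
#' @export
setClass("McResult",
    representation(detections = "data.frame", ledger = "numeric",
                   absorption = "arrayOrNULL", ssp = "list", paths = "list",
                   fluence = "arrayOrNULL", config = "SimulationConfig"))

#' Univariate mixture-of-Gaussians model
#'
#' Fitted by \code{\link{fitMog}} via EM; components may be mapped to tissue
#' codes for maximum-probability classification.
#'
#' @slot means component means.
#' @slot variances component variances.
#' @slot weights mixing weights (sum to 1).
#' @slot tissues integer tissue code per component (NA until assigned).
#' @slot logLik log-likelihood trace across EM iterations.
#' @slot flagged TRUE if any component variance was floored.
#' @export
setClass("MixtureModel",
    representation(means = "numeric", variances = "numeric",
                   weights = "numeric", tissues = "integer",
                   logLik = "numeric", flagged = "logical"),
    validity = function(object) {
        msg <- NULL
        K <- length(object@means)
        if (K < 1) msg <- c(msg, "need at least one component")
        if (length(object@variances) != K || any(object@variances <= 0))
            msg <- c(msg, "variances must be positive, one per component")
        if (length(object@weights) != K || any(object@weights < 0) ||
            abs(sum(object@weights) - 1) > 1e-8)
            msg <- c(msg, "weights must be non-negative and sum to 1")
        if (is.null(msg)) TRUE else msg
    })

#' Spatial sensitivity profile volume
#'
#' Per-voxel accumulated traversal weight (path length times exit weight) of
#' detected photons for one detector; the "banana" map of where detected
#' light sampled the head.
#'
#' @slot values numeric 3-D array, entries >= 0.
#' @slot detector detector index the profile belongs to.
#' @slot normalized TRUE if the volume was scaled to unit sum.
#' @slot status "ok" or "empty" (no detections at this detector).
#' @export
setClass("SensitivityVolume",
    representation(values = "array", detector = "integer",
                   normalized = "logical", status = "character"),
    validity = function(object) {
        if (any(object@values < 0)) "entries must be >= 0" else TRUE
    })
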