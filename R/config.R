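#' @include AllClasses.R phantoms.R simulate.R analysis.R segment.R
NULL

# documented configuration schema: defaults and validators per section
.configSchema <- function() {
    pos <- function(x) is.numeric(x) && all(x > 0)
    nonneg <- function(x) is.numeric(x) && all(x >= 0)
    list(
        seed = list(default = 1, check = function(x)
            is.numeric(x) && length(x) == 1 && x == round(x),
            msg = "seed must be a single integer"),
        out_dir = list(default = "nirsmc-out", check = is.character,
            msg = "out_dir must be a path"),
        log_level = list(default = "info", check = function(x)
            x %in% c("quiet", "info", "debug"),
            msg = "log_level must be quiet, info or debug"),
        phantom = list(default = list(
            kind = "folded-head", dims = c(256L, 256L, 92L),
            voxel_size = 1, scalp = 3, skull = 7, csf = 2, gray = 4,
            csf_expansion = 1, sulcus_count = 8L),
            check = function(x) is.list(x), msg = "phantom must be a map"),
        segmentation = list(default = list(
            sigma = 1.5, mog_seed = 1),
            check = function(x) is.list(x), msg = "segmentation must be a map"),
        simulation = list(default = list(
            photons = 1e5, wavelength = 800, mode = "reduced",
            gate_ps = 1000, bin_ps = 1, detector_radius = 5,
            separations_cm = 1:10, view = "transverse",
            source_depth_mm = 60),
            check = function(x) is.list(x) &&
                (is.null(x$photons) || (pos(x$photons) && x$photons >= 1)) &&
                (is.null(x$gate_ps) || pos(x$gate_ps)) &&
                (is.null(x$detector_radius) || pos(x$detector_radius)) &&
                (is.null(x$separations_cm) || nonneg(x$separations_cm)),
            msg = "simulation: photons must be >= 1, gate_ps and detector_radius > 0"),
        analysis = list(default = list(ratio_method = "deepest"),
            check = function(x) is.list(x) &&
                (is.null(x$ratio_method) ||
                 x$ratio_method %in% c("deepest", "pathlength")),
            msg = "analysis: ratio_method must be deepest or pathlength"))
}

#' Parse and validate a run configuration
#'
#' Reads a YAML configuration with sections phantom / segmentation /
#' simulation / analysis plus a master seed, applies documented defaults,
#' and rejects unknown keys. Every defaulted field is echoed into the run
#' manifest, so an output directory is reproducible from its manifest
#' alone.
#'
#' @param path YAML file path, or NULL to start from defaults.
#' @param overrides named list merged over the file values (CLI flags).
#' @return the resolved configuration (named list, class
#'   \code{"RunConfig"}).
#' @export
parseConfig <- function(path = NULL, overrides = list()) {
    schema <- .configSchema()
    raw <- if (is.null(path)) list() else yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    unknown <- setdiff(names(raw), names(schema))
    if (length(unknown))
        stop(sprintf("unknown configuration key(s): %s",
                     paste(unknown, collapse = ", ")))
    cfg <- list()
    for (key in names(schema)) {
        val <- raw[[key]]
        def <- schema[[key]]$default
        val <- if (is.null(val)) def
               else if (is.list(def)) {
                   unknown2 <- setdiff(names(val), names(def))
                   if (length(unknown2))
                       stop(sprintf("unknown key(s) in section '%s': %s",
                                    key, paste(unknown2, collapse = ", ")))
                   utils::modifyList(def, val)
               } else val
        cfg[[key]] <- val
    }
    for (nm in names(overrides)) {
        parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
        if (length(parts) == 1) cfg[[parts]] <- overrides[[nm]]
        else cfg[[parts[1]]][[parts[2]]] <- overrides[[nm]]
    }
    for (key in names(schema)) {
        if (!schema[[key]]$check(cfg[[key]]))
            stop(sprintf("invalid configuration at '%s': %s", key,
                         schema[[key]]$msg))
    }
    structure(cfg, class = "RunConfig")
}

#' Write the run manifest
#'
#' JSON record of the fully resolved configuration, package version,
#' wall-clock metadata and input-file checksums: sufficient to re-run a
#' result bit-identically.
#'
#' @param cfg a resolved \code{\link{parseConfig}} list.
#' @param dir output directory.
#' @param inputs character vector of input file paths to checksum.
#' @return the manifest path, invisibly.
#' @export
writeManifest <- function(cfg, dir, inputs = character(0)) {
    manifest <- list(
        config = unclass(cfg),
        package = "nirsmc",
        version = as.character(utils::packageVersion("nirsmc")),
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        inputs = if (length(inputs))
            as.list(tools::md5sum(inputs)) else list())
    path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' Re-create a RunConfig from a manifest
#'
#' @param path manifest.json path.
#' @return the \code{"RunConfig"} list stored in the manifest.
#' @export
readManifest <- function(path) {
    man <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- man$config
    # round-trip: re-validate through the schema
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(cfg, tmp)
    parseConfig(tmp)
}

.logMsg <- function(cfg, level, ...) {
    levels <- c(quiet = 0, info = 1, debug = 2)
    if (levels[[cfg$log_level]] >= levels[[level]])
        message(sprintf(...))
    invisible(NULL)
}

#' Build the phantom described by a RunConfig
#'
#' @param cfg a \code{\link{parseConfig}} result.
#' @return a \linkS4class{LabelVolume}.
#' @export
phantomFromConfig <- function(cfg) {
    p <- cfg$phantom
    th <- c(scalp = p$scalp, skull = p$skull, csf = p$csf, gray = p$gray)
    if (identical(p$kind, "layered-slab"))
        makeLayeredSlabPhantom(layeredSlabSpec(
            dims = p$dims, voxelSize = p$voxel_size, thicknesses = th))
    else
        makeFoldedHeadPhantom(foldedHeadSpec(
            dims = p$dims, voxelSize = p$voxel_size, thicknesses = th,
            csfExpansion = p$csf_expansion,
            sulcusCount = p$sulcus_count))
}

#' Run the full pipeline described by a RunConfig
#'
#' phantom (or segmentation of a supplied volume) -> simulation ->
#' analysis; writes curves, detections and the run manifest into
#' \code{cfg$out_dir}.
#'
#' @param cfg a \code{\link{parseConfig}} result.
#' @param volume optional \linkS4class{LabelVolume} to use instead of the
#'   configured phantom.
#' @return list(result, intensity, ratios, cross) invisibly.
#' @export
runPipeline <- function(cfg, volume = NULL) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (is.null(volume)) {
        .logMsg(cfg, "info", "building %s phantom", cfg$phantom$kind)
        volume <- phantomFromConfig(cfg)
    }
    s <- cfg$simulation
    layout <- buildProbeLayout(volume, separationsCm = s$separations_cm,
                               view = s$view,
                               sourceDepthMm = s$source_depth_mm,
                               detRadiusMm = s$detector_radius)
    scfg <- simulationConfig(volume, layout, nPhotons = s$photons,
                             seed = cfg$seed, wavelength = s$wavelength,
                             scatteringMode = s$mode,
                             maxTimePs = s$gate_ps, binWidthPs = s$bin_ps)
    .logMsg(cfg, "info", "simulating %g photons at %g nm (seed %d)",
            s$photons, s$wavelength, cfg$seed)
    res <- runSimulation(scfg)
    led <- res@ledger
    .logMsg(cfg, "info",
            "detected %d packets; conservation imbalance %.3g",
            as.integer(led[["n_detected"]]), conservationError(res))
    intens <- intensityVsSeparation(res)
    cp <- crossPoint(res, method = cfg$analysis$ratio_method)
    utils::write.table(intens, file.path(cfg$out_dir, "intensity.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cp$curves, file.path(cfg$out_dir, "ratios.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeDetections(res, file.path(cfg$out_dir, "detections.tsv"))
    writeManifest(cfg, cfg$out_dir)
    invisible(list(result = res, intensity = intens, ratios = cp$curves,
                   cross = cp$cross))
}
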