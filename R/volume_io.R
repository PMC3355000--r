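#' @include AllClasses.R volumes.R
NULL

#' Read and write voxel volumes
#'
#' Volumes are stored either as NIfTI (\code{.nii} / \code{.nii.gz}; voxel
#' size in \code{pixdim}, origin in the qform offset, label volumes tagged
#' via \code{intent_name = "labels"}) or as raw little-endian binary plus a
#' plain-text YAML sidecar (\code{<path>.yaml}) holding dims, voxel size,
#' origin, dtype and kind. Round trips reproduce grid, voxel size and origin
#' exactly for integer labels.
#'
#' @param volume a \linkS4class{LabelVolume} or \linkS4class{ScalarVolume}.
#' @param path output path; extension selects the format (\code{.nii},
#'   \code{.nii.gz} or \code{.raw}).
#' @return \code{readVolume} returns a \code{LabelVolume} or
#'   \code{ScalarVolume} according to the stored kind.
#' @export
#' @examples
#' lv <- makeLayeredSlabPhantom(layeredSlabSpec(dims = c(8, 8, 12)))
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(lv, f)
#' identical(tissueLabels(readVolume(f)), tissueLabels(lv))
writeVolume <- function(volume, path) {
    isLabel <- methods::is(volume, "LabelVolume")
    if (!isLabel && !methods::is(volume, "ScalarVolume"))
        stop("volume must be a LabelVolume or ScalarVolume")
    dat <- if (isLabel) volume@labels else volume@intensities
    if (grepl("\\.nii(\\.gz)?$", path)) {
        ref <- list(pixdim = c(-1, volume@voxelSize, 0, 0, 0, 0),
                    qoffset_x = volume@origin[1],
                    qoffset_y = volume@origin[2],
                    qoffset_z = volume@origin[3],
                    qform_code = 1L,
                    intent_name = if (isLabel) "labels" else "intensity")
        img <- RNifti::asNifti(dat, reference = ref)
        RNifti::writeNifti(img, path,
                           datatype = if (isLabel) "uint8" else "float")
    } else if (grepl("\\.raw$", path)) {
        meta <- list(kind = if (isLabel) "labels" else "intensity",
                     dims = as.integer(dim(dat)),
                     voxel_size = as.numeric(volume@voxelSize),
                     origin = as.numeric(volume@origin),
                     dtype = if (isLabel) "int32" else "float64",
                     endian = "little")
        yaml::write_yaml(meta, paste0(path, ".yaml"))
        con <- file(path, "wb")
        on.exit(close(con))
        if (isLabel) writeBin(as.integer(dat), con, size = 4L,
                              endian = "little")
        else writeBin(as.double(dat), con, size = 8L, endian = "little")
    } else {
        stop("unsupported volume format: use .nii, .nii.gz or .raw")
    }
    invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
    if (grepl("\\.nii(\\.gz)?$", path)) {
        img <- RNifti::readNifti(path)
        hdr <- RNifti::niftiHeader(img)
        vs <- RNifti::pixdim(img)[1:3]
        org <- c(hdr$qoffset_x, hdr$qoffset_y, hdr$qoffset_z)
        dat <- array(as.numeric(img), dim = dim(img)[1:3])
        isLabel <- identical(hdr$intent_name, "labels") ||
            (nchar(hdr$intent_name) == 0 &&
             all(dat == round(dat)) && all(dat >= 0) && all(dat <= 5))
    } else if (grepl("\\.raw$", path)) {
        metaPath <- paste0(path, ".yaml")
        if (!file.exists(metaPath))
            stop(sprintf("missing sidecar metadata file '%s'", metaPath))
        meta <- yaml::read_yaml(metaPath)
        for (k in c("kind", "dims", "voxel_size", "dtype"))
            if (is.null(meta[[k]]))
                stop(sprintf("sidecar is missing required field '%s'", k))
        n <- prod(meta$dims)
        con <- file(path, "rb")
        on.exit(close(con))
        dat <- if (meta$dtype == "int32")
            readBin(con, "integer", n, size = 4L, endian = "little")
        else readBin(con, "double", n, size = 8L, endian = "little")
        dat <- array(as.numeric(dat), dim = meta$dims)
        vs <- as.numeric(meta$voxel_size)
        org <- if (is.null(meta$origin)) c(0, 0, 0) else as.numeric(meta$origin)
        isLabel <- identical(meta$kind, "labels")
    } else {
        stop("unsupported volume format: use .nii, .nii.gz or .raw")
    }
    if (isLabel) {
        bad <- setdiff(unique(as.vector(dat)), 0:5)
        if (length(bad))
            stop(sprintf("label file contains unknown tissue code(s): %s",
                         paste(sort(bad), collapse = ", ")))
        LabelVolume(array(as.integer(dat), dim = dim(dat)), vs, org)
    } else {
        ScalarVolume(dat, vs, org)
    }
}
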