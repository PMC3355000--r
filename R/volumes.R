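#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a LabelVolume
#'
#' @param labels integer 3-D array of tissue codes 0..5.
#' @param voxelSize physical voxel edge lengths in mm (length 1 or 3).
#' @param origin physical position (mm) of the first voxel's corner.
#' @return a \linkS4class{LabelVolume}.
#' @export
#' @examples
#' lv <- LabelVolume(array(0L, c(4, 4, 2)))
#' gridDim(lv)
LabelVolume <- function(labels, voxelSize = c(1, 1, 1), origin = c(0, 0, 0)) {
    storage.mode(labels) <- "integer"
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    methods::new("LabelVolume", labels = labels,
                 voxelSize = as.numeric(voxelSize),
                 origin = as.numeric(origin))
}

#' Construct a ScalarVolume
#'
#' @param intensities numeric 3-D array.
#' @param voxelSize voxel edge lengths in mm (length 1 or 3).
#' @param origin position (mm) of the first voxel's corner.
#' @return a \linkS4class{ScalarVolume}.
#' @export
ScalarVolume <- function(intensities, voxelSize = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
    storage.mode(intensities) <- "double"
    if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
    methods::new("ScalarVolume", intensities = intensities,
                 voxelSize = as.numeric(voxelSize),
                 origin = as.numeric(origin))
}

#' @rdname volume-accessors
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
#' @rdname volume-accessors
setMethod("voxelSize", "ScalarVolume", function(x) x@voxelSize)
#' @rdname volume-accessors
setMethod("origin", "LabelVolume", function(x) x@origin)
#' @rdname volume-accessors
setMethod("origin", "ScalarVolume", function(x) x@origin)
#' @rdname volume-accessors
setMethod("gridDim", "LabelVolume", function(x) dim(x@labels))
#' @rdname volume-accessors
setMethod("gridDim", "ScalarVolume", function(x) dim(x@intensities))

#' @rdname volume-accessors
setMethod("axialDepth", "LabelVolume",
          function(x) dim(x@labels)[3] * x@voxelSize[3])
#' @rdname volume-accessors
setMethod("axialDepth", "ScalarVolume",
          function(x) dim(x@intensities)[3] * x@voxelSize[3])

#' @rdname LabelVolume-class
setMethod("tissueLabels", "LabelVolume", function(x) x@labels)

#' @rdname ScalarVolume-class
setMethod("intensities", "ScalarVolume", function(x) x@intensities)

setMethod("show", "LabelVolume", function(object) {
    d <- dim(object@labels)
    cat(sprintf("LabelVolume: %d x %d x %d voxels @ %g x %g x %g mm\n",
                d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
                object@voxelSize[3]))
    cat(sprintf("  axial depth %.1f cm\n", axialDepth(object) / 10))
    counts <- tabulate(as.vector(object@labels) + 1L, nbins = 6L)
    cat("  voxels per tissue:\n")
    for (i in seq_len(6))
        if (counts[i] > 0)
            cat(sprintf("    %-6s %d\n", tissueNames()[i], counts[i]))
    invisible(NULL)
})

setMethod("show", "ScalarVolume", function(object) {
    d <- dim(object@intensities)
    cat(sprintf("ScalarVolume: %d x %d x %d voxels @ %g x %g x %g mm, range [%.3g, %.3g]\n",
                d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
                object@voxelSize[3], min(object@intensities),
                max(object@intensities)))
    invisible(NULL)
})

setMethod("show", "SensitivityVolume", function(object) {
    cat(sprintf("SensitivityVolume (detector %d, %s%s): total %.4g over %d voxels\n",
                object@detector,
                if (object@normalized) "normalized" else "raw",
                if (identical(object@status, "empty")) ", EMPTY" else "",
                sum(object@values), sum(object@values > 0)))
    invisible(NULL)
})

# run a block with a locally seeded RNG, restoring global state afterwards
withLocalSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}
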