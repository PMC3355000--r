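#' @include AllClasses.R
NULL

#' Accessors for voxel volumes
#'
#' @param x a \linkS4class{LabelVolume}, \linkS4class{ScalarVolume} or
#'   \linkS4class{SensitivityVolume}.
#' @return \code{voxelSize} and \code{origin} return numeric vectors of
#'   length 3 (mm); \code{gridDim} returns the integer grid dimensions;
#'   \code{axialDepth} returns the physical depth of the slice stack in mm.
#' @name volume-accessors
#' @aliases voxelSize origin gridDim axialDepth
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname volume-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname volume-accessors
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname volume-accessors
#' @export
setGeneric("axialDepth", function(x) standardGeneric("axialDepth"))

#' @rdname LabelVolume-class
#' @param x a \code{LabelVolume}
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname ScalarVolume-class
#' @param x a \code{ScalarVolume}
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname McResult-class
#' @param x an \code{McResult}
#' @export
setGeneric("detections", function(x) standardGeneric("detections"))

#' @rdname McResult-class
#' @export
setGeneric("ledger", function(x) standardGeneric("ledger"))
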