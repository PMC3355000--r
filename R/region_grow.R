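#' @include AllClasses.R
NULL

#' Seeded region growing by flood fill
#'
#' Starting from ordered seed points, each seed floods the connected
#' component of the binary foreground mask it lies in, under the chosen
#' connectivity. Components are labeled in seed order (so with the default
#' head pipeline seeds, scalp = 1 and skull = 2); when two seeds share a
#' component the first seed's label wins; unreached foreground stays 0.
#'
#' @param mask logical array (2-D matrix or 3-D array); TRUE = foreground.
#' @param seeds integer matrix of 1-based seed coordinates, one row per
#'   seed (2 columns for a matrix mask, 3 for an array).
#' @param connectivity 6, 18 or 26 neighbours in 3-D; for a single-slice
#'   mask these collapse to 4 (conn = 6) or 8 (conn = 26) in-plane.
#' @return integer array of the mask shape holding seed labels (0 =
#'   unreached or background).
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:4, 2:4] <- TRUE
#' regionGrow(m, matrix(c(3, 3), 1))
regionGrow <- function(mask, seeds, connectivity = 6) {
    d <- dim(mask)
    if (is.null(d)) stop("mask must be a matrix or 3-D array")
    if (length(d) == 2L) {
        d <- c(d, 1L)
        if (ncol(seeds) == 2L) seeds <- cbind(seeds, 1L)
    }
    if (length(d) != 3L) stop("mask must be 2-D or 3-D")
    seeds <- matrix(as.integer(seeds), nrow = nrow(seeds))
    lab <- cpp_region_grow(as.logical(mask), as.integer(d), seeds,
                           as.integer(connectivity))
    array(lab, dim = dim(mask))
}
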