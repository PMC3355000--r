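#' @include AllClasses.R
NULL

# Neumann (replicated) boundary for a 2-D field
.padNeumann <- function(m) {
    m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
    cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

# central differences on a 2-D grid (unit spacing)
.gradX <- function(m) {
    p <- .padNeumann(m)
    (p[2:(nrow(m) + 1) + 1, 2:(ncol(m) + 1)] -
     p[2:(nrow(m) + 1) - 1, 2:(ncol(m) + 1)]) / 2
}

.gradY <- function(m) {
    p <- .padNeumann(m)
    (p[2:(nrow(m) + 1), 2:(ncol(m) + 1) + 1] -
     p[2:(nrow(m) + 1), 2:(ncol(m) + 1) - 1]) / 2
}

.laplacian <- function(m) {
    p <- .padNeumann(m)
    i <- 2:(nrow(m) + 1); j <- 2:(ncol(m) + 1)
    p[i + 1, j] + p[i - 1, j] + p[i, j + 1] + p[i, j - 1] - 4 * m
}

#' Edge indicator of an image
#'
#' \code{g = 1 / (1 + |grad(G_sigma * I)|^2)}: close to 1 in flat regions
#' and small on strong edges. The gradient uses central differences on the
#' Gaussian-smoothed image (no smoothing when \code{sigma = 0}).
#'
#' @param img numeric matrix (one image slice).
#' @param sigma Gaussian kernel standard deviation in pixels (>= 0).
#' @return matrix with values in (0, 1].
#' @export
#' @examples
#' g <- edgeIndicator(matrix(1, 16, 16), sigma = 1)
#' all(g == 1)
edgeIndicator <- function(img, sigma = 1.5) {
    if (!is.matrix(img)) stop("img must be a matrix")
    if (any(!is.finite(img))) stop("image contains non-finite values")
    if (sigma < 0) stop("sigma must be >= 0")
    sm <- if (sigma > 0)
        EBImage::gblur(img, sigma = sigma, boundary = "replicate")
    else img
    1 / (1 + .gradX(sm)^2 + .gradY(sm)^2)
}

#' Level-set evolution parameters
#'
#' Parameters of the distance-regularized variational level-set flow: the
#' signed-distance penalty weight \code{muPen}, the edge-weighted contour
#' length weight \code{lambdaLen}, the signed area weight \code{nuArea}
#' (positive shrinks the interior region phi < 0, negative expands it), the
#' Gaussian scale of the edge indicator, the evolution time step, the
#' regularization half-width of the smoothed Dirac/Heaviside pair, and the
#' iteration budget with a contour-change stopping tolerance.
#'
#' @param muPen distance-penalty weight, > 0.
#' @param lambdaLen contour-length weight, > 0.
#' @param nuArea area weight (sign selects shrink/expand).
#' @param sigmaGauss edge-indicator Gaussian sigma (pixels).
#' @param tauStep explicit time step; stability needs tauStep * muPen < 0.25.
#' @param epsReg Dirac/Heaviside regularization half-width (pixels).
#' @param nIter iteration budget.
#' @param tol stop when the interior region changes by fewer than this many
#'   pixels between checks.
#' @param checkEvery iterations between stopping checks.
#' @return a validated list of class \code{"LevelSetParams"}.
#' @export
levelSetParams <- function(muPen = 0.2, lambdaLen = 5, nuArea = 1.5,
                           sigmaGauss = 1.5, tauStep = 1, epsReg = 1.5,
                           nIter = 600, tol = 2, checkEvery = 20) {
    if (muPen <= 0) stop("muPen must be > 0")
    if (lambdaLen <= 0) stop("lambdaLen must be > 0")
    if (epsReg <= 0) stop("epsReg must be > 0")
    if (tauStep * muPen >= 0.25)
        stop("stability requires tauStep * muPen < 0.25")
    structure(list(muPen = muPen, lambdaLen = lambdaLen, nuArea = nuArea,
                   sigmaGauss = sigmaGauss, tauStep = tauStep,
                   epsReg = epsReg, nIter = nIter, tol = tol,
                   checkEvery = checkEvery),
              class = "LevelSetParams")
}

# smoothed Dirac delta: (1/(2 eps)) (1 + cos(pi x / eps)) on |x| <= eps
.diracEps <- function(x, eps) {
    out <- (1 + cos(pi * x / eps)) / (2 * eps)
    out[abs(x) > eps] <- 0
    out
}

#' Initialize a binary-step level-set field
#'
#' @param dims c(nrows, ncols) of the image.
#' @param type "border" places the interior everywhere except a margin frame
#'   (used to shrink onto an outer contour); "disk" places a small interior
#'   disk at \code{center} (used to expand from a point inside).
#' @param margin frame width for "border" (pixels).
#' @param center,radius disk center and radius for "disk".
#' @param c0 step height.
#' @return matrix phi0 with negative values inside.
#' @export
initialLevelSet <- function(dims, type = c("border", "disk"), margin = 3,
                            center = dims / 2, radius = 3, c0 = 2) {
    type <- match.arg(type)
    phi <- matrix(c0, dims[1], dims[2])
    if (type == "border") {
        phi[(margin + 1):(dims[1] - margin),
            (margin + 1):(dims[2] - margin)] <- -c0
    } else {
        rows <- matrix(seq_len(dims[1]), dims[1], dims[2])
        cols <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
        phi[(rows - center[1])^2 + (cols - center[2])^2 <= radius^2] <- -c0
    }
    phi
}

#' Evolve a level-set contour on an image
#'
#' Gradient flow of the distance-regularized variational energy: a penalty
#' term keeps phi close to a signed distance function (replacing periodic
#' re-initialization), an edge-weighted length term attracts the zero level
#' set to image edges, and a weighted area term drives expansion or
#' shrinkage. The flow is discretized with central differences and an
#' explicit time step.
#'
#' @param img numeric matrix (image slice).
#' @param phi0 initial level-set field (negative inside); see
#'   \code{\link{initialLevelSet}}.
#' @param params a \code{\link{levelSetParams}} list.
#' @param g optional precomputed edge indicator (else computed from
#'   \code{img} with \code{params$sigmaGauss}).
#' @return the evolved field, with attributes \code{iterations} and
#'   \code{converged}.
#' @export
evolveLevelSet <- function(img, phi0, params = levelSetParams(), g = NULL) {
    if (!inherits(params, "LevelSetParams")) params <- do.call(levelSetParams, params)
    if (any(!is.finite(phi0))) stop("phi0 must be finite")
    if (is.null(g)) g <- edgeIndicator(img, params$sigmaGauss)
    gx <- .gradX(g); gy <- .gradY(g)
    phi <- phi0
    if (params$nIter == 0) {
        attr(phi, "iterations") <- 0L
        attr(phi, "converged") <- FALSE
        return(phi)
    }
    prevRegion <- phi < 0
    converged <- FALSE
    iter <- 0L
    while (iter < params$nIter) {
        iter <- iter + 1L
        px <- .gradX(phi); py <- .gradY(phi)
        mag <- sqrt(px^2 + py^2)
        magS <- pmax(mag, 1e-10)
        nxv <- px / magS; nyv <- py / magS
        curv <- .gradX(nxv) + .gradY(nyv)          # div(grad phi / |grad phi|)
        distReg <- .laplacian(phi) - curv          # penalty flow
        edgeTerm <- .gradX(g * nxv) + .gradY(g * nyv)  # div(g grad phi/|.|)
        dd <- .diracEps(phi, params$epsReg)
        phi <- phi + params$tauStep *
            (params$muPen * distReg +
             params$lambdaLen * dd * edgeTerm +
             params$nuArea * g * dd)
        if (any(!is.finite(phi)))
            stop(sprintf("level-set evolution diverged at iteration %d", iter))
        if (iter %% params$checkEvery == 0L) {
            region <- phi < 0
            if (sum(xor(region, prevRegion)) < params$tol) {
                converged <- TRUE
                break
            }
            prevRegion <- region
        }
    }
    attr(phi, "iterations") <- iter
    attr(phi, "converged") <- converged
    phi
}

#' Extract the region enclosed by the zero level set
#'
#' Under the package sign convention negative phi is inside.
#'
#' @param phi level-set field (matrix).
#' @return list with \code{mask} (logical matrix, TRUE inside) and
#'   \code{status}: "ok" when an interface exists, "no_interface" when the
#'   field has a single sign (empty or full mask).
#' @export
extractZeroLevelRegion <- function(phi) {
    if (any(!is.finite(phi))) stop("phi must be finite")
    mask <- phi < 0
    status <- if (all(mask) || !any(mask)) "no_interface" else "ok"
    list(mask = mask, status = status)
}
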