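#' @include AllClasses.R volumes.R
NULL

#' Fit a univariate mixture of Gaussians by EM
#'
#' Maximizes the mixture likelihood of intensities under K Gaussian
#' components with mixing weights. The EM log-likelihood is non-decreasing
#' across iterations; the fit stops when its change drops below \code{tol}.
#' A component whose variance collapses below \code{varFloor} is floored and
#' the model flagged.
#'
#' @param samples numeric vector of intensities.
#' @param K number of components (K >= 1; needs at least K distinct values).
#' @param seed RNG seed for the jittered quantile initialization.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxIter iteration budget.
#' @param varFloor lower bound for component variances.
#' @return a \linkS4class{MixtureModel}; the log-likelihood trace is in the
#'   \code{logLik} slot.
#' @export
#' @examples
#' m <- fitMog(c(rnorm(200), rnorm(200, 8)), K = 2)
#' sort(m@means)
fitMog <- function(samples, K, seed = 1, tol = 1e-10, maxIter = 500,
                   varFloor = 1e-12) {
    samples <- as.numeric(samples)
    if (any(!is.finite(samples))) stop("samples must be finite")
    n <- length(samples)
    if (K > n) stop("K exceeds the sample count")
    if (length(unique(samples)) < K)
        stop("need at least K distinct sample values")
    # jittered quantile initialization, seeded
    init <- withLocalSeed(seed, {
        qs <- stats::quantile(samples, probs = (seq_len(K) - 0.5) / K,
                              names = FALSE)
        spread <- max(stats::sd(samples), 1e-6)
        qs + stats::rnorm(K, 0, 1e-3 * spread)
    })
    mu <- init
    v <- rep(max(stats::var(samples) / K^2, varFloor), K)
    w <- rep(1 / K, K)
    flagged <- FALSE
    llTrace <- numeric(0)
    llPrev <- -Inf
    for (it in seq_len(maxIter)) {
        dens <- vapply(seq_len(K), function(k)
            w[k] * stats::dnorm(samples, mu[k], sqrt(v[k])), numeric(n))
        dens <- matrix(dens, nrow = n)
        rowTot <- rowSums(dens)
        rowTot[rowTot < 1e-300] <- 1e-300
        ll <- sum(log(rowTot))
        llTrace <- c(llTrace, ll)
        resp <- dens / rowTot
        nk <- colSums(resp)
        nk[nk < 1e-300] <- 1e-300
        mu <- colSums(resp * samples) / nk
        v <- vapply(seq_len(K), function(k)
            sum(resp[, k] * (samples - mu[k])^2) / nk[k], numeric(1))
        if (any(v < varFloor)) {
            v[v < varFloor] <- varFloor
            flagged <- TRUE
        }
        w <- nk / n
        w <- w / sum(w)
        if (is.finite(llPrev) && abs(ll - llPrev) < tol) break
        llPrev <- ll
    }
    methods::new("MixtureModel", means = mu, variances = v, weights = w,
                 tissues = rep(NA_integer_, K), logLik = llTrace,
                 flagged = flagged)
}

#' Assign tissue codes to mixture components
#'
#' Components are ranked by ascending mean intensity and mapped to tissue
#' codes in the supplied order (default T1 ordering inside the skull: CSF
#' darkest, then gray, then white matter).
#'
#' @param model a \linkS4class{MixtureModel}.
#' @param order tissue codes for the components in ascending-mean order.
#' @return the model with its \code{tissues} slot filled.
#' @export
assignTissues <- function(model, order = c(3L, 4L, 5L)) {
    if (length(order) != length(model@means))
        stop("need one tissue code per component")
    model@tissues[rank(model@means, ties.method = "first")] <-
        as.integer(order)
    model
}

#' Maximum-probability tissue classification
#'
#' Each masked voxel is assigned the tissue of the component with the
#' largest posterior probability (mixing weight times Gaussian density).
#' Ties break toward the lower tissue code.
#'
#' @param img a \linkS4class{ScalarVolume} (or numeric array).
#' @param model a \linkS4class{MixtureModel} with tissues assigned.
#' @param mask logical array marking the voxels to classify.
#' @return integer array: tissue codes inside the mask, 0 outside.
#' @export
classifyMaxProb <- function(img, model, mask) {
    arr <- if (methods::is(img, "ScalarVolume")) img@intensities else img
    if (any(is.na(model@tissues)))
        stop("model components have no tissue assignment; see assignTissues()")
    y <- arr[mask]
    if (any(!is.finite(y))) stop("masked intensities must be finite")
    K <- length(model@means)
    # columns ordered by ascending tissue code so that ties pick the lower code
    ord <- order(model@tissues)
    post <- vapply(ord, function(k)
        model@weights[k] * stats::dnorm(y, model@means[k],
                                        sqrt(model@variances[k])),
        numeric(length(y)))
    post <- matrix(post, ncol = K)
    pick <- max.col(post, ties.method = "first")
    out <- array(0L, dim = dim(arr))
    out[mask] <- model@tissues[ord][pick]
    out
}

setMethod("show", "MixtureModel", function(object) {
    K <- length(object@means)
    cat(sprintf("MixtureModel: %d component(s), %d EM iteration(s)%s\n",
                K, length(object@logLik),
                if (object@flagged) " [variance floored]" else ""))
    df <- data.frame(mean = object@means, sd = sqrt(object@variances),
                     weight = object@weights, tissue = object@tissues)
    print(df, row.names = FALSE, digits = 4)
    invisible(NULL)
})
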