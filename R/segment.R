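#' @include AllClasses.R level_set.R mixture.R region_grow.R
NULL

#' Parameters of the five-layer segmentation pipeline
#'
#' @param levelSet a \code{\link{levelSetParams}} list shared by the outer
#'   (scalp) and inner (intracranial) contour evolutions.
#' @param nuOuter area weight for the shrinking outer contour (> 0).
#' @param nuInner area weight for the expanding inner contour (< 0).
#' @param bandWidth half-width (pixels) of the boundary band refined by
#'   intensity thresholding after each level-set stage.
#' @param mogSeed seed for the mixture fits.
#' @param subsample at most this many voxels are used to fit each mixture
#'   (classification always uses all voxels).
#' @param t1Order tissue codes of the intracranial mixture components in
#'   ascending-mean order (default: CSF darkest, then gray, then white).
#' @return a list of class \code{"SegmentationParams"}.
#' @export
segmentationParams <- function(levelSet = levelSetParams(),
                               nuOuter = 1.5, nuInner = -1.5,
                               bandWidth = 2, mogSeed = 1,
                               subsample = 20000,
                               t1Order = c(3L, 4L, 5L)) {
    structure(list(levelSet = levelSet, nuOuter = nuOuter,
                   nuInner = nuInner, bandWidth = bandWidth,
                   mogSeed = mogSeed, subsample = subsample,
                   t1Order = as.integer(t1Order)),
              class = "SegmentationParams")
}

# largest connected component of a 2-D mask, holes filled
.cleanMask2d <- function(mask) {
    if (!any(mask)) return(mask)
    lab <- EBImage::bwlabel(mask)
    counts <- tabulate(lab[lab > 0])
    keep <- lab == which.max(counts)
    as.matrix(EBImage::fillHull(keep)) > 0
}

.dilate2d <- function(mask, r) {
    as.matrix(EBImage::dilate(mask, EBImage::makeBrush(2 * r + 1,
                                                       "diamond"))) > 0
}

.erode2d <- function(mask, r) {
    as.matrix(EBImage::erode(mask, EBImage::makeBrush(2 * r + 1,
                                                      "diamond"))) > 0
}

# shrink a border-initialized contour onto the head outline of one slice,
# then snap the boundary within a narrow band by intensity threshold
.headMaskSlice <- function(I, p) {
    ls <- p$levelSet; ls$nuArea <- abs(p$nuOuter)
    phi0 <- initialLevelSet(dim(I), "border", margin = 2)
    phi <- evolveLevelSet(I, phi0, ls)
    reg <- extractZeroLevelRegion(phi)
    if (reg$status == "no_interface") return(NULL)
    mask <- .cleanMask2d(reg$mask)
    if (!any(mask)) return(NULL)
    band <- .dilate2d(mask, p$bandWidth) & !.erode2d(mask, p$bandWidth)
    if (any(band)) {
        # snap the contour within the band by a voxelwise intensity rule:
        # air and the outermost tissue layer are far apart in T1 contrast
        ringIn <- mask & !.erode2d(mask, p$bandWidth + 2)
        mOut <- mean(I[!mask & !band])
        mIn <- mean(I[ringIn])
        if (is.finite(mOut) && is.finite(mIn) && mIn != mOut) {
            thr <- (mOut + mIn) / 2
            mask[band] <- if (mIn > mOut) I[band] > thr else I[band] < thr
        }
        mask <- .cleanMask2d(mask)
    }
    mask
}

# expand a seed disk inside the skull-membership image S up to the inner
# skull boundary of one slice
.innerMaskSlice <- function(S, head, p) {
    if (!any(head)) return(head & FALSE)
    idx <- which(head, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    if (!head[ctr[1], ctr[2]] || S[ctr[1], ctr[2]] > 0.5)
        return(head & FALSE)   # no intracranial content in this slice
    ls <- p$levelSet; ls$nuArea <- -abs(p$nuInner)
    # seed large enough that the length term cannot collapse the disk
    rSeed <- max(3, min(8, round(0.3 * sqrt(sum(head) / pi))))
    phi0 <- initialLevelSet(dim(S), "disk", center = ctr, radius = rSeed)
    # scale the unit-amplitude membership map so its boundaries register in
    # the edge indicator like ordinary image edges
    phi <- evolveLevelSet(100 * S, phi0, ls)
    reg <- extractZeroLevelRegion(phi)
    if (reg$status == "no_interface") return(head & FALSE)
    mask <- .cleanMask2d(reg$mask) & head
    band <- .dilate2d(mask, p$bandWidth) & !.erode2d(mask, p$bandWidth)
    mask[band] <- S[band] < 0.5 & head[band]
    .cleanMask2d(mask)
}

#' Segment a T1-like volume into the five-layer head model
#'
#' Two-stage pipeline. Stage 1 finds the scalp outer contour by a level set
#' shrinking from the image border and the inner skull boundary by a level
#' set expanding from a point inside, run slice by slice and stacked; region
#' growing then labels the connected scalp (= 1) and skull (= 2) layers of
#' the resulting shell, split by a mixture-based intensity threshold.
#' Stage 2 fits a K = 3 mixture of Gaussians to the intracranial
#' intensities and assigns CSF (= 3), gray (= 4) and white matter (= 5) by
#' maximum posterior probability, with components mapped to tissues by
#' ascending mean intensity (T1 ordering). Background stays 0.
#'
#' @param img a \linkS4class{ScalarVolume} with head-like contrast
#'   (background darker than tissue).
#' @param params a \code{\link{segmentationParams}} list.
#' @return a \linkS4class{LabelVolume} on the grid of \code{img}.
#' @export
segmentFiveLayers <- function(img, params = segmentationParams()) {
    stopifnot(methods::is(img, "ScalarVolume"))
    arr <- img@intensities
    d <- dim(arr)
    if (diff(range(arr)) < 1e-12)
        stop("no contour: the image is constant")

    # ---- stage 1a: head mask per slice (outer scalp contour) ----
    head <- array(FALSE, dim = d)
    for (zi in seq_len(d[3])) {
        m <- .headMaskSlice(arr[, , zi], params)
        if (!is.null(m)) head[, , zi] <- m
    }
    if (!any(head))
        stop("no contour: the outer level set found no closed scalp contour")

    # ---- intensity structure of the head: K = 4 mixture ----
    hv <- arr[head]
    sub <- if (length(hv) > params$subsample)
        withLocalSeed(params$mogSeed,
                      sample(hv, params$subsample)) else hv
    mog4 <- fitMog(sub, K = 4, seed = params$mogSeed)
    ord <- order(mog4@means)
    muSkull <- mog4@means[ord][2]
    # posterior skull membership per voxel
    dens <- vapply(seq_len(4), function(k)
        mog4@weights[k] * stats::dnorm(as.vector(arr), mog4@means[k],
                                       sqrt(mog4@variances[k])),
        numeric(length(arr)))
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    Svec <- dens[, ord[2]] / tot
    S <- array(Svec, dim = d)

    # ---- stage 1b: intracranial mask per slice (inner skull boundary) ----
    intra <- array(FALSE, dim = d)
    for (zi in seq_len(d[3])) {
        if (!any(head[, , zi])) next
        intra[, , zi] <- .innerMaskSlice(S[, , zi], head[, , zi], params)
    }

    shell <- head & !intra
    # ---- scalp/skull split of the shell + region growing ----
    muBright <- max(mog4@means)
    thrShell <- (muSkull + muBright) / 2
    scalpMask <- shell & arr > thrShell
    skullMask <- shell & !scalpMask
    labels <- array(0L, dim = d)
    seedOf <- function(mask) {
        idx <- which(mask, arr.ind = TRUE)
        idx[which.max(idx[, 1]), , drop = FALSE]   # outermost (+x) voxel
    }
    if (any(scalpMask) && any(skullMask)) {
        scalpReached <- regionGrow(scalpMask, seedOf(scalpMask), 26) > 0
        skullReached <- regionGrow(skullMask, seedOf(skullMask), 26) > 0
        labels[scalpReached] <- 1L
        labels[skullReached] <- 2L
        # stray shell voxels disconnected from both seeds: intensity rule
        stray <- shell & labels == 0L
        labels[stray & arr > thrShell] <- 1L
        labels[stray & arr <= thrShell] <- 2L
    } else {
        labels[scalpMask] <- 1L
        labels[skullMask] <- 2L
    }

    # ---- stage 2: CSF / gray / white by maximum posterior ----
    if (any(intra)) {
        iv <- arr[intra]
        subI <- if (length(iv) > params$subsample)
            withLocalSeed(params$mogSeed + 1,
                          sample(iv, params$subsample)) else iv
        mog3 <- fitMog(subI, K = 3, seed = params$mogSeed)
        mog3 <- assignTissues(mog3, params$t1Order)
        cls <- classifyMaxProb(arr, mog3, intra)
        labels[intra] <- cls[intra]
    }
    LabelVolume(labels, img@voxelSize, img@origin)
}
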