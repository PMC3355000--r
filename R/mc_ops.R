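#' @include AllClasses.R tissue_table.R
NULL

# vacuum speed of light, mm/ps
.C_MM_PS <- 0.299792458

#' Sample a photon free-path step length
#'
#' Inverse-CDF sampling of the exponential step-size density
#' \code{p(s) = mu_t exp(-mu_t s)}: \code{s = -ln(1 - xi) / mu_t}.
#'
#' @param xi uniform random number(s) in [0, 1).
#' @param muT total interaction (extinction) coefficient, mm^-1, > 0.
#' @return step length(s) in mm.
#' @export
#' @examples
#' sampleStep(1 - exp(-1), 1)  # exactly 1 mm
sampleStep <- function(xi, muT) {
    if (any(muT <= 0)) stop("muT must be > 0")
    if (any(xi < 0 | xi >= 1)) stop("xi must lie in [0, 1)")
    -log(1 - xi) / muT
}

#' Sample a Henyey-Greenstein scattering deflection
#'
#' Draws the polar deflection cosine from the Henyey-Greenstein phase
#' function by its closed-form inverse CDF (uniform on [-1, 1] when g = 0)
#' and an isotropic azimuth \code{psi = 2 pi xi}, then rotates the packet
#' direction in its local frame.
#'
#' @param direction current unit direction (length 3).
#' @param xiTheta,xiPsi uniform random numbers in [0, 1).
#' @param g anisotropy factor, -1 < g < 1.
#' @return list with \code{cosTheta}, \code{psi} and the rotated unit
#'   \code{direction}.
#' @export
sampleScatter <- function(direction, xiTheta, xiPsi, g) {
    if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)")
    ct <- cpp_hg_cos(xiTheta, g)
    psi <- 2 * pi * xiPsi
    list(cosTheta = ct, psi = psi,
         direction = cpp_rotate_direction(direction, ct, psi))
}

#' Seeded bulk draws of Henyey-Greenstein deflection cosines
#'
#' @param n number of draws.
#' @param g anisotropy factor.
#' @param seed RNG seed (uses the package's photon-stream generator).
#' @return numeric vector of cos(theta) draws.
#' @export
hgDraws <- function(n, g, seed = 1) {
    if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)")
    cpp_hg_draws(as.integer(n), g, as.numeric(seed))
}

#' Deposit absorbed weight at an interaction
#'
#' The packet drops \code{dw = w mu_a / mu_t} of its weight into the
#' current voxel.
#'
#' @param w current packet weight.
#' @param muA absorption coefficient (mm^-1).
#' @param muT total interaction coefficient (mm^-1), > 0.
#' @return list with \code{deltaW} (deposited) and \code{weight} (updated).
#' @export
absorbWeight <- function(w, muA, muT) {
    if (any(muT <= 0)) stop("muT must be > 0")
    dw <- w * muA / muT
    list(deltaW = dw, weight = w - dw)
}

#' Unpolarized Fresnel reflectance at a refractive-index step
#'
#' @param cosI cosine of the incidence angle (> 0).
#' @param nIn,nOut refractive indices of the incidence and transmission
#'   media.
#' @return reflectance in [0, 1]; 1 beyond the critical angle.
#' @export
#' @examples
#' fresnelReflectance(1, 1.4, 1)  # (0.4 / 2.4)^2
fresnelReflectance <- function(cosI, nIn, nOut) {
    cpp_fresnel(cosI, nIn, nOut)
}

#' Surface interaction of an outbound packet
#'
#' Applies Snell's law and the unpolarized Fresnel reflectance at a
#' boundary: beyond the critical angle the packet reflects deterministically
#' (total internal reflection); otherwise it reflects specularly with
#' probability R, else exits with the refracted direction carrying its full
#' current weight (binary survival).
#'
#' @param direction outbound unit direction.
#' @param normal outward unit surface normal.
#' @param nIn,nOut refractive indices inside / outside.
#' @param xi uniform random number deciding reflection.
#' @return list with \code{type} ("reflect" or "exit"), the new unit
#'   \code{direction} and the Fresnel \code{reflectance}.
#' @export
surfaceInteraction <- function(direction, normal, nIn, nOut, xi) {
    if (abs(sqrt(sum(normal^2)) - 1) > 1e-6)
        stop("normal must be a unit vector")
    ci <- sum(direction * normal)
    if (ci <= 0) stop("packet must be outbound (direction . normal > 0)")
    R <- cpp_fresnel(ci, nIn, nOut)
    if (xi < R) {
        list(type = "reflect",
             direction = direction - 2 * ci * normal,
             reflectance = R)
    } else {
        tang <- direction - ci * normal
        st <- sqrt(max(0, sum(tang^2))) * nIn / nOut
        ct <- sqrt(max(0, 1 - st^2))
        tangN <- sqrt(sum(tang^2))
        refr <- if (tangN > 1e-12) tang / tangN * st + ct * normal
                else normal
        refr <- refr / sqrt(sum(refr^2))
        list(type = "exit", direction = refr, reflectance = R)
    }
}

#' Russian-roulette packet termination
#'
#' Unbiased termination of low-weight packets: below \code{threshold} the
#' packet survives with probability \code{surviveProb} (weight boosted by
#' 1/surviveProb), else terminates with its residual weight reported so
#' that conservation audits close.
#'
#' @param w current weight.
#' @param threshold roulette trigger weight.
#' @param surviveProb survival probability in (0, 1].
#' @param xi uniform random number.
#' @return list(alive, weight, terminatedWeight).
#' @export
rouletteStep <- function(w, threshold, surviveProb, xi) {
    if (surviveProb <= 0 || surviveProb > 1)
        stop("surviveProb must lie in (0, 1]")
    if (w >= threshold)
        return(list(alive = TRUE, weight = w, terminatedWeight = 0))
    if (xi < surviveProb)
        list(alive = TRUE, weight = w / surviveProb, terminatedWeight = 0)
    else
        list(alive = FALSE, weight = 0, terminatedWeight = w)
}

# per-code mu_t vector (index = code + 1 handled C side as code index)
.muVectors <- function(table, wavelength, mode) {
    tb <- table@table
    tb <- tb[tb$wavelength_nm == wavelength, , drop = FALSE]
    if (nrow(tb) == 0)
        stop(sprintf("wavelength %g nm not present in the optical table",
                     wavelength))
    muA <- muS <- g <- numeric(6)
    n <- c(1, rep(NA_real_, 5))
    for (i in seq_len(nrow(tb))) {
        code <- tb$code[i]
        muA[code + 1] <- tb$mu_a_mm[i]
        muS[code + 1] <- if (mode == "physical")
            musFromReduced(tb$mu_s_reduced_mm[i], tb$g[i])
        else tb$mu_s_reduced_mm[i]
        g[code + 1] <- if (mode == "physical") tb$g[i] else tb$g[i]
        n[code + 1] <- tb$n[i]
    }
    list(muA = muA, muS = muS, g = g, n = n)
}

#' Construct a photon packet
#'
#' @param position position in mm (length 3).
#' @param direction unit propagation direction (length 3).
#' @param weight packet weight in (0, 1].
#' @param timePs elapsed flight time (ps).
#' @return a list of class \code{"PhotonPacket"} with zeroed per-tissue
#'   partial paths and visited mask.
#' @export
photonPacket <- function(position, direction, weight = 1, timePs = 0) {
    nrm <- sqrt(sum(direction^2))
    if (abs(nrm - 1) > 1e-9) direction <- direction / nrm
    if (weight <= 0 || weight > 1) stop("weight must lie in (0, 1]")
    structure(list(position = as.numeric(position),
                   direction = as.numeric(direction),
                   weight = weight, timePs = timePs,
                   partialPath = numeric(5), visitedMask = 0L,
                   alive = TRUE),
              class = "PhotonPacket")
}

#' Advance a packet through the voxel grid until it spends an
#' optical-depth budget
#'
#' Marches the packet ray voxel by voxel with exact axis-crossing
#' distances, consuming \code{mu_t(i) * s(i)} of the budget in each voxel,
#' and stops either at the interaction site where the budget is exactly
#' spent or on an air/tissue surface. Per-tissue partial paths, the
#' visited-layer mask and the elapsed time (using the local refractive
#' index) are accumulated along the way.
#'
#' @param packet a \code{\link{photonPacket}}.
#' @param lv a \linkS4class{LabelVolume}.
#' @param table an \linkS4class{OpticalTable}.
#' @param budget optical-depth budget (dimensionless, > 0), typically
#'   \code{-log(xi)}.
#' @param wavelength nm (must be in the table).
#' @param scatteringMode "reduced" or "physical".
#' @return list with \code{outcome} ("interaction" or "surface"), the
#'   updated packet, the voxel index, the tissue code there and (for
#'   surface hits) the outward face normal.
#' @export
advanceThroughVoxels <- function(packet, lv, table, budget,
                                 wavelength = 800,
                                 scatteringMode = c("reduced", "physical")) {
    scatteringMode <- match.arg(scatteringMode)
    stopifnot(inherits(packet, "PhotonPacket"), methods::is(lv, "LabelVolume"))
    mu <- .muVectors(table, wavelength, scatteringMode)
    res <- cpp_advance_packet(packet$position, packet$direction,
                              packet$timePs, packet$partialPath,
                              packet$visitedMask, budget,
                              as.vector(lv@labels), dim(lv@labels),
                              lv@voxelSize, mu$muA + mu$muS, mu$n)
    packet$position <- res$position
    packet$direction <- res$direction
    packet$timePs <- res$time_ps
    packet$partialPath <- res$partial_path
    packet$visitedMask <- res$visited_mask
    list(outcome = res$outcome, packet = packet, voxel = res$voxel,
         tissue = res$tissue, normal = res$normal)
}
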