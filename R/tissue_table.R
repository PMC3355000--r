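#' @include AllClasses.R
NULL

# Published brain-tissue optical properties. The 690/780/830 nm block is
# printed in cm^-1 (mu_a / mu_s') and converted to mm^-1 on ingest; white
# matter duplicates gray matter at those wavelengths exactly as printed.
# The 800 nm block is quoted directly in mm^-1 (mu_s' / mu_a). A single
# anisotropy factor g = 0.92 applies to all five tissues.
.tissueData <- function() {
    cm <- function(x) x / 10
    rows <- list(
        # wavelength, tissue code, mu_a (mm^-1), mu_s' (mm^-1)
        list(690, 1, cm(0.159), cm(8)),
        list(690, 2, cm(0.101), cm(10)),
        list(690, 3, cm(0.004), cm(0.1)),
        list(690, 4, cm(0.178), cm(12.5)),
        list(690, 5, cm(0.178), cm(12.5)),
        list(780, 1, cm(0.164), cm(7.1)),
        list(780, 2, cm(0.115), cm(9.1)),
        list(780, 3, cm(0.017), cm(0.1)),
        list(780, 4, cm(0.170), cm(11.6)),
        list(780, 5, cm(0.170), cm(11.6)),
        list(830, 1, cm(0.191), cm(6.6)),
        list(830, 2, cm(0.136), cm(8.6)),
        list(830, 3, cm(0.026), cm(0.1)),
        list(830, 4, cm(0.186), cm(11.1)),
        list(830, 5, cm(0.186), cm(11.1)),
        list(800, 1, 0.018, 1.9),
        list(800, 2, 0.016, 1.6),
        list(800, 3, 0.004, 0.24),
        list(800, 4, 0.036, 2.2),
        list(800, 5, 0.014, 9.1))
    do.call(rbind, lapply(rows, function(r)
        data.frame(wavelength_nm = r[[1]], code = r[[2]],
                   mu_a_mm = r[[3]], mu_s_reduced_mm = r[[4]])))
}

#' Build the tissue optical-property table
#'
#' Returns the per-tissue optical properties at the supported wavelengths
#' 690, 780, 830 and 800 nm, in mm^-1. The anisotropy factor is 0.92 for all
#' tissues; the published table announces refractive indices without printing
#' them, so a configurable default of 1.4 (tissue) / 1.0 (air) is used.
#'
#' @param wavelengths wavelengths (nm) to include; must be a subset of
#'   \{690, 780, 800, 830\}.
#' @param n refractive index for all tissues (air is fixed at 1), or a named
#'   vector over \code{c("scalp","skull","csf","gray","white")}.
#' @param g anisotropy factor applied to all tissues.
#' @return an \linkS4class{OpticalTable}.
#' @export
#' @examples
#' tab <- buildTissueTable()
#' opticalProperties(tab, "csf", 690)$mu_a_mm   # 0.0004 mm^-1
buildTissueTable <- function(wavelengths = c(690, 780, 800, 830), n = 1.4,
                             g = 0.92) {
    supported <- c(690, 780, 800, 830)
    bad <- setdiff(wavelengths, supported)
    if (length(bad))
        stop(sprintf("unsupported wavelength(s) %s; supported: {%s} nm",
                     paste(bad, collapse = ", "),
                     paste(supported, collapse = ", ")))
    tb <- .tissueData()
    tb <- tb[tb$wavelength_nm %in% wavelengths, , drop = FALSE]
    tb$g <- g
    tnames <- tissueNames()[tb$code + 1L]
    if (length(n) == 1L) {
        tb$n <- n
    } else {
        if (!all(tnames %in% names(n)))
            stop("named refractive indices must cover all five tissues")
        tb$n <- as.numeric(n[tnames])
    }
    tb$tissue <- tnames
    tb <- tb[c("tissue", "code", "wavelength_nm", "mu_a_mm",
               "mu_s_reduced_mm", "g", "n")]
    rownames(tb) <- NULL
    methods::new("OpticalTable", table = tb)
}

#' Look up optical properties of one tissue at one wavelength
#'
#' @param table an \linkS4class{OpticalTable}.
#' @param tissue tissue name ("scalp", "skull", "csf", "gray", "white") or
#'   code 1..5.
#' @param wavelength nm.
#' @return one-row data.frame with mu_a_mm, mu_s_reduced_mm, g, n.
#' @export
opticalProperties <- function(table, tissue, wavelength) {
    stopifnot(methods::is(table, "OpticalTable"))
    tb <- table@table
    code <- if (is.numeric(tissue)) as.integer(tissue)
            else tissueCodes()[[match.arg(tissue, tissueNames()[-1])]]
    row <- tb[tb$code == code & tb$wavelength_nm == wavelength, , drop = FALSE]
    if (nrow(row) == 0L)
        stop(sprintf("no entry for tissue %s at %g nm; table holds {%s} nm",
                     tissue, wavelength,
                     paste(sort(unique(tb$wavelength_nm)), collapse = ", ")))
    row
}

#' Scattering coefficient from its reduced form
#'
#' Similarity relation \code{mu_s = mu_s' / (1 - g)}, needed because the
#' bundled table stores reduced scattering coefficients while the transport
#' kernel can sample an anisotropic Henyey-Greenstein phase function.
#'
#' @param muSReduced reduced scattering coefficient (mm^-1).
#' @param g anisotropy factor, 0 <= g < 1.
#' @return mu_s in mm^-1.
#' @export
#' @examples
#' musFromReduced(0.01, 0.92)  # 0.125 mm^-1
musFromReduced <- function(muSReduced, g) {
    if (any(g >= 1) || any(g < 0))
        stop("musFromReduced requires 0 <= g < 1")
    muSReduced / (1 - g)
}

#' Export / import the tissue table as delimited text
#'
#' @param table an \linkS4class{OpticalTable}.
#' @param path file path for the tab-separated table.
#' @return \code{readTissueTable} returns an \linkS4class{OpticalTable}.
#' @export
exportTissueTable <- function(table, path) {
    stopifnot(methods::is(table, "OpticalTable"))
    utils::write.table(table@table, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

#' @rdname exportTissueTable
#' @export
readTissueTable <- function(path) {
    tb <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    methods::new("OpticalTable", table = tb)
}

setMethod("show", "OpticalTable", function(object) {
    cat(sprintf("OpticalTable: %d tissues x %d wavelengths (mm^-1)\n",
                length(unique(object@table$code)),
                length(unique(object@table$wavelength_nm))))
    print(object@table, row.names = FALSE)
    invisible(NULL)
})
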