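# Embedded snapshot of standard atomic isotope masses (Da) and natural
# abundances (fractions), so all mass arithmetic is reproducible offline.
# Values are the CODATA/IUPAC recommended ones commonly tabulated for
# small-molecule mass spectrometry.
.ISOTOPES <- local({
    iso <- function(element, mass, abundance) {
        data.frame(element = element, mass = mass, abundance = abundance)
    }
    tab <- rbind(
        iso("H",  c(1.00782503207, 2.01410177785), c(0.999885, 0.000115)),
        iso("C",  c(12.0000000000, 13.00335483507), c(0.9893, 0.0107)),
        iso("N",  c(14.00307400443, 15.00010889888), c(0.99636, 0.00364)),
        iso("O",  c(15.99491461957, 16.99913175650, 17.99915961286),
                  c(0.99757, 0.00038, 0.00205)),
        iso("F",  18.99840316273, 1.0),
        iso("Si", c(27.97692653465, 28.97649466490, 29.97377013600),
                  c(0.92223, 0.04685, 0.03092)),
        iso("P",  30.97376199842, 1.0),
        iso("S",  c(31.97207117440, 32.97145890980, 33.96786700400,
                    35.96708071000),
                  c(0.9499, 0.0075, 0.0425, 0.0001)),
        iso("Cl", c(34.96885268200, 36.96590260200), c(0.7576, 0.2424)),
        iso("Br", c(78.91833760000, 80.91628970000), c(0.5069, 0.4931)),
        iso("I",  126.90447190000, 1.0)
    )
    # most abundant isotope first within each element
    tab <- do.call(rbind, lapply(split(tab, tab$element), function(d) {
        d[order(-d$abundance), , drop = FALSE]
    }))
    rownames(tab) <- NULL
    tab
})

# physical constants (Da)
.ELECTRON_MASS <- 0.00054857990907
.PROTON_MASS   <- 1.00727646627

#' Isotope table used by all mass computations
#'
#' Returns the embedded snapshot of isotope masses and natural abundances.
#' Within each element, isotopes are ordered by decreasing abundance, so the
#' first row per element is the most abundant isotope used for monoisotopic
#' ("most abundant isotope") masses.
#'
#' @return A `data.frame` with columns `element`, `mass` (Da) and
#'   `abundance` (fraction summing to 1 within each element).
#' @examples
#' head(isotopeTable())
#' @export
isotopeTable <- function() .ISOTOPES

.knownElements <- function() unique(.ISOTOPES$element)

.elementIsotopes <- function(symbol) {
    .ISOTOPES[.ISOTOPES$element == symbol, , drop = FALSE]
}
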