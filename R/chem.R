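# Molecular formulas, adduct masses and theoretical isotope patterns.

# condition helper used across the package: input/validation problems carry
# the class "mdscreenInputError" so callers (and the CLI) can map them to a
# dedicated exit status.
.inputError <- function(msg, call. = FALSE) {
    stop(structure(class = c("mdscreenInputError", "error", "condition"),
                   list(message = msg, call = if (call.) sys.call(-1))))
}

#' Parse a Hill-notation molecular formula
#'
#' Reads a plain elemental formula such as `"C10H8"` or `"C6Cl6"` into a
#' named integer vector of element counts. Element symbols must exist in the
#' embedded isotope table (see [isotopeTable()]); repeated symbols are
#' summed. The result is returned in Hill order (C, H, then alphabetical).
#'
#' @param text A single non-empty formula string.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C10H8")
#' parseFormula("C12H18Br2Cl2")
#' @export
parseFormula <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(text))
        .inputError("formula must be a single non-empty string")
    known <- .knownElements()
    rest <- text
    pos <- 1L
    counts <- integer(0)
    while (nzchar(rest)) {
        m <- regexpr("^([A-Z][a-z]?)([0-9]*)", rest)
        if (m == -1L || attr(m, "match.length") == 0L)
            .inputError(sprintf(
                "malformed formula '%s': unexpected character at position %d",
                text, pos))
        tok <- regmatches(rest, m)
        sym <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
        num <- sub("^[A-Z][a-z]?", "", tok)
        if (!sym %in% known)
            .inputError(sprintf("unknown element \"%s\" in formula '%s'",
                                sym, text))
        n <- if (nzchar(num)) as.integer(num) else 1L
        if (is.na(n) || n < 1L)
            .inputError(sprintf(
                "element %s has invalid count in formula '%s'", sym, text))
        counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
        pos <- pos + nchar(tok)
        rest <- substr(rest, nchar(tok) + 1L, nchar(rest))
    }
    .hillOrder(counts)
}

.hillOrder <- function(counts) {
    syms <- names(counts)
    lead <- intersect(c("C", "H"), syms)
    counts[c(lead, sort(setdiff(syms, lead)))]
}

# accept either a formula string or an already-parsed count vector
.asFormula <- function(f) {
    if (is.character(f)) return(parseFormula(f))
    if (is.numeric(f) && !is.null(names(f))) {
        bad <- setdiff(names(f), .knownElements())
        if (length(bad))
            .inputError(sprintf("unknown element \"%s\"", bad[1L]))
        if (any(f < 1) || length(f) == 0L)
            .inputError("all element counts must be >= 1")
        return(.hillOrder(as.integer(round(f)) |> stats::setNames(names(f))))
    }
    .inputError("formula must be a string or a named count vector")
}

#' Render element counts back to a Hill-notation string
#'
#' @param counts Named integer vector as returned by [parseFormula()].
#' @return Formula string.
#' @export
formulaToString <- function(counts) {
    counts <- .asFormula(counts)
    paste0(names(counts), ifelse(counts > 1L, counts, ""), collapse = "")
}

#' Monoisotopic (most-abundant-isotope) neutral mass
#'
#' Sums, over all elements, the element count times the mass of that
#' element's most abundant isotope. For the elements covered here the most
#' abundant isotope is also the lightest, so this is the conventional
#' monoisotopic mass.
#'
#' @param f Formula string or named count vector.
#' @return Neutral mass in Da.
#' @examples
#' monoisotopicMass("C10H8")   # naphthalene, 128.0626
#' monoisotopicMass("C6Cl6")   # hexachlorobenzene, 281.8131
#' @export
monoisotopicMass <- function(f) {
    counts <- .asFormula(f)
    masses <- vapply(names(counts),
                     function(s) .elementIsotopes(s)$mass[1L], numeric(1))
    sum(counts * masses)
}

#' Adduct kinds and their fixed mass shifts
#'
#' The three (quasi-)molecular ions produced by GC-APCI charge/proton
#' transfer: the radical cation `M+.` (neutral minus one electron), the
#' protonated ion `[M+H]+` (neutral plus a proton) and the deprotonated ion
#' `[M-H]-` (neutral minus a proton). Electron mass is handled explicitly so
#' that m/z values are correct at the sub-mDa level required by the 2 mDa
#' mass gate.
#'
#' @return `adductKinds()` returns the vector of supported kind names.
#' @export
adductKinds <- function() c("radical_cation", "protonated", "deprotonated")

#' @rdname adductKinds
#' @param kind One of `"radical_cation"`, `"protonated"`, `"deprotonated"`.
#' @return `adductMassShift()` returns the fixed m/z shift in Da applied to
#'   the neutral mass.
#' @export
adductMassShift <- function(kind) {
    kind <- match.arg(kind, adductKinds())
    switch(kind,
           radical_cation = -.ELECTRON_MASS,
           protonated     = +.PROTON_MASS,
           deprotonated   = -.PROTON_MASS)
}

#' Theoretical m/z of a singly charged adduct
#'
#' @param f Formula string or named count vector.
#' @param kind Adduct kind, see [adductKinds()].
#' @return m/z in Da (charge 1).
#' @examples
#' adductMz("C10H8", "protonated")      # 129.0699
#' adductMz("C10H8", "radical_cation")  # 128.0621
#' @export
adductMz <- function(f, kind) {
    monoisotopicMass(f) + adductMassShift(kind)
}

# isotopologue distribution of `n` atoms of one element: multinomial
# expansion over its isotopes, pruned below `prune` absolute abundance.
.elementDistribution <- function(symbol, n, prune = 1e-12) {
    iso <- .elementIsotopes(symbol)
    k <- nrow(iso)
    if (k == 1L) return(list(mass = n * iso$mass, ab = 1))
    comps <- .compositions(n, k)
    ab <- apply(comps, 1L, function(cts)
        stats::dmultinom(cts, prob = iso$abundance))
    mass <- as.numeric(comps %*% iso$mass)
    keep <- ab >= prune
    list(mass = mass[keep], ab = ab[keep])
}

# all k-part non-negative integer compositions of n (rows sum to n)
.compositions <- function(n, k) {
    if (k == 1L) return(matrix(n, ncol = 1L))
    do.call(rbind, lapply(0:n, function(i)
        cbind(i, .compositions(n - i, k - 1L))))
}

# convolve two sparse mass/abundance distributions
.convolveDistributions <- function(a, b, prune = 1e-12) {
    mass <- outer(a$mass, b$mass, "+")
    ab <- outer(a$ab, b$ab)
    keep <- ab >= prune
    out <- list(mass = mass[keep], ab = ab[keep])
    if (length(out$ab) > 20000L) {                   # safety: compress fine structure
        key <- round(out$mass * 1e6)
        ab <- vapply(split(out$ab, key), sum, numeric(1))
        m <- vapply(split(out$mass * out$ab, key), sum, numeric(1)) / ab
        out <- list(mass = unname(m), ab = unname(ab))
    }
    out
}

#' Theoretical isotope pattern of a (quasi-)molecular ion
#'
#' Computes the isotopologue distribution of a formula by per-element
#' multinomial expansion convolved across elements, aggregates the fine
#' structure into nominal-mass-spaced centroids (intensity-weighted mean
#' mass per aggregate, matching centroided instrument envelopes), applies
#' the adduct m/z shift, normalizes the base peak to 100 and prunes.
#'
#' The proton added in `[M+H]+` is treated as pure 1H and contributes no
#' envelope term of its own; its effect is far below the 5 percent intensity
#' gate.
#'
#' @param f Formula string or named count vector.
#' @param kind Adduct kind, see [adductKinds()].
#' @param minRelIntensity Prune peaks below this relative intensity
#'   (percent of base), in `[0, 100)`. Default 1.
#' @param maxPeaks Keep at most this many most-intense peaks (>= 2).
#'   Default 8.
#' @return A `data.frame` with columns `mz` (Da, ascending) and `relint`
#'   (percent of base peak, base = 100), with attribute `singlePeak` set to
#'   `TRUE` when the formula contains only single-isotope elements (so the
#'   isotope gate can be bypassed).
#' @examples
#' isotopePattern("Cl2")                    # M, M+2, M+4 at 100 : 64 : 10.2
#' isotopePattern("C6Cl6", "radical_cation")
#' @export
isotopePattern <- function(f, kind = "radical_cation",
                           minRelIntensity = 1, maxPeaks = 8) {
    if (minRelIntensity < 0 || minRelIntensity >= 100)
        .inputError("minRelIntensity must be in [0, 100)")
    if (maxPeaks < 2)
        .inputError("maxPeaks must be at least 2")
    counts <- .asFormula(f)
    kind <- match.arg(kind, adductKinds())
    dist <- list(mass = 0, ab = 1)
    for (el in names(counts))
        dist <- .convolveDistributions(dist,
                                       .elementDistribution(el, counts[[el]]))
    mono <- monoisotopicMass(counts)
    offset <- round(dist$mass - mono)
    ab <- vapply(split(dist$ab, offset), sum, numeric(1))
    mz <- vapply(split(dist$mass * dist$ab, offset), sum, numeric(1)) / ab +
        adductMassShift(kind)
    relint <- 100 * ab / max(ab)
    keep <- relint >= minRelIntensity
    mz <- mz[keep]; relint <- relint[keep]
    if (length(mz) > maxPeaks) {
        top <- order(relint, decreasing = TRUE)[seq_len(maxPeaks)]
        mz <- mz[top]; relint <- relint[top]
    }
    ord <- order(mz)
    out <- data.frame(mz = unname(mz[ord]), relint = unname(relint[ord]))
    attr(out, "singlePeak") <- nrow(out) == 1L
    out
}
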