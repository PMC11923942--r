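# Shared fixtures and the independent brute-force isotope oracle.

# Exhaustive enumeration over per-atom isotope assignments, aggregated
# into nominal-mass centroids. Deliberately independent of the package's
# convolution path: it walks every assignment explicitly.
bruteForcePattern <- function(counts, kind = "radical_cation") {
    tab <- isotopeTable()
    atoms <- rep(names(counts), counts)
    dist <- data.frame(mass = 0, ab = 1)
    for (a in atoms) {
        iso <- tab[tab$element == a, , drop = FALSE]
        dist <- do.call(rbind, lapply(seq_len(nrow(iso)), function(j)
            data.frame(mass = dist$mass + iso$mass[j],
                       ab = dist$ab * iso$abundance[j])))
    }
    mono <- sum(vapply(names(counts), function(el)
        counts[[el]] * tab$mass[tab$element == el][1L], numeric(1)))
    off <- round(dist$mass - mono)
    ab <- tapply(dist$ab, off, sum)
    mz <- tapply(dist$mass * dist$ab, off, sum) / ab +
        adductMassShift(kind)
    out <- data.frame(mz = as.numeric(mz), relint = 100 * as.numeric(ab) /
                          max(ab))
    out[order(out$mz), ]
}

# small hand-built library: naphthalene, hexachlorobenzene, BDE-47-like
toyLibrary <- function() {
    suspectLibrary(data.frame(
        suspect_id = c("NAP", "HCB", "BDE"),
        inchikey = c("UFWIBTONFRDIAS", "CKAPSXZOOQJIBF", "WHPWVWPNGVXYSY"),
        formula = c("C10H8", "C6Cl6", "C12H6Br2O"),
        rt_minutes = c(10, 15, 25),
        rt_source = "literature_converted",
        ccs_a2 = c(124, 152, 185),
        ccs_source = "literature",
        stringsAsFactors = FALSE))
}

# a feature that matches a toy library entry exactly in all dimensions
exactFeature <- function(library, suspectId, adduct = "radical_cation",
                         featureId = "F1", nFragments = 3L,
                         rtOffset = 0, ccsFactor = 1) {
    e <- suspectEntries(library)
    e <- e[e$suspect_id == suspectId, ]
    env <- isotopePattern(e$formula, adduct)
    frg <- if (nFragments > 0L)
        data.frame(mz = seq(51, by = 13, length.out = nFragments),
                   intensity = rep(1e4, nFragments))
    else data.frame(mz = numeric(0), intensity = numeric(0))
    row <- data.frame(feature_id = featureId,
                      mz = adductMz(e$formula, adduct),
                      rt_minutes = e$rt_minutes + rtOffset,
                      ccs_a2 = e$ccs_a2 * ccsFactor,
                      intensity = 1e5, stringsAsFactors = FALSE)
    row$isotope_envelope <- I(list(env))
    row$ms2_fragments <- I(list(frg))
    row
}

toyFeatureSet <- function(...) featureSet(do.call(rbind, list(...)))

# all formulas over the given elements with a bounded total atom count
allSmallFormulas <- function(elements = c("C", "H", "Cl", "Br"),
                             maxAtoms = 8L) {
    grid <- expand.grid(rep(list(0:maxAtoms), length(elements)))
    names(grid) <- elements
    grid <- grid[rowSums(grid) >= 1L & rowSums(grid) <= maxAtoms, ,
                 drop = FALSE]
    lapply(seq_len(nrow(grid)), function(i) {
        counts <- unlist(grid[i, ])
        counts[counts > 0L]
    })
}
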