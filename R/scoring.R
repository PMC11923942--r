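# MS1 gates and the continuous scoring system.

#' Exact-mass gate
#'
#' Applies the split mass rule: for theoretical m/z at or above the rule
#' boundary (default 200 Da) the error must be below `massTolPpm` ppm; for
#' lighter ions it must be below `massTolMda` mDa. At exactly the boundary
#' the ppm rule applies (there 5 ppm equals 1 mDa, the stricter of the two
#' readings). Both comparisons are strict.
#'
#' @param measuredMz,theoreticalMz m/z in Da (vectors recycle).
#' @param config A [ScoringConfig-class].
#' @return `data.frame` with columns `pass`, `ppm`, `mda` (signed errors,
#'   measured minus theoretical).
#' @examples
#' cfg <- scoringConfig()
#' massGate(300.0012, 300.0000, cfg)  # 4 ppm, pass
#' massGate(150.0019, 150.0000, cfg)  # 1.9 mDa, pass
#' @export
massGate <- function(measuredMz, theoreticalMz, config = scoringConfig()) {
    if (any(measuredMz <= 0) || any(theoreticalMz <= 0))
        .inputError("m/z values must be positive")
    n <- max(length(measuredMz), length(theoreticalMz))
    measuredMz <- rep_len(measuredMz, n)
    theoreticalMz <- rep_len(theoreticalMz, n)
    dmda <- (measuredMz - theoreticalMz) * 1e3
    dppm <- (measuredMz - theoreticalMz) / theoreticalMz * 1e6
    useppm <- theoreticalMz >= config@massRuleBoundary
    pass <- ifelse(useppm, abs(dppm) < config@massTolPpm,
                   abs(dmda) < config@massTolMda)
    data.frame(pass = pass, ppm = dppm, mda = dmda)
}

#' Isotope-pattern gate
#'
#' Pairs measured envelope peaks to the theoretical isotopologues by
#' nearest m/z within the active mass tolerance, requires at least
#' `minIsotopeIons` matched non-base isotope ions, computes per-isotope
#' relative intensity deviations (percent of the theoretical intensity)
#' and gates on their geometric mean being strictly below
#' `isotopeMaxGmDeviation`. All matched theoretical isotopes enter the
#' geometric mean. A single-peak theoretical pattern (compound of
#' single-isotope elements only) passes vacuously with `bypass = TRUE`.
#'
#' @param envelope Measured envelope, `data.frame` with `mz` and `relint`
#'   (percent of base).
#' @param theory Theoretical pattern from [isotopePattern()].
#' @param config A [ScoringConfig-class].
#' @return List with `pass`, `gmDeviation` (percent, `NA` on bypass),
#'   `nMatched` and `bypass`.
#' @export
isotopeGate <- function(envelope, theory, config = scoringConfig()) {
    if (nrow(theory) < 1L)
        .inputError("theoretical pattern must contain at least one peak")
    if (nrow(theory) == 1L)
        return(list(pass = TRUE, gmDeviation = NA_real_, nMatched = 0L,
                    bypass = TRUE))
    base <- which.max(theory$relint)
    nonBase <- theory[-base, , drop = FALSE]
    devs <- numeric(0)
    if (nrow(envelope)) {
        for (j in seq_len(nrow(nonBase))) {
            tol <- if (nonBase$mz[j] >= config@massRuleBoundary)
                config@massTolPpm * 1e-6 * nonBase$mz[j]
            else config@massTolMda * 1e-3
            d <- abs(envelope$mz - nonBase$mz[j])
            k <- which.min(d)
            if (d[k] <= tol)
                devs <- c(devs, abs(envelope$relint[k] - nonBase$relint[j]) /
                              nonBase$relint[j] * 100)
        }
    }
    if (length(devs) < max(config@minIsotopeIons, 1L))
        return(list(pass = FALSE, gmDeviation = NA_real_,
                    nMatched = length(devs), bypass = FALSE))
    gm <- if (any(devs == 0)) 0 else exp(mean(log(devs)))
    list(pass = gm < config@isotopeMaxGmDeviation, gmDeviation = gm,
         nMatched = length(devs), bypass = FALSE)
}

#' RT and CCS differences
#'
#' `deltaRt()` is the signed difference in minutes (measured minus
#' reference; the sign matters because the RT intervals are asymmetric).
#' `deltaCcs()` is the signed relative difference in percent of the
#' reference CCS.
#'
#' @param measured,reference Positive numerics (vectors recycle).
#' @return Numeric vector of differences.
#' @examples
#' deltaRt(10.5, 10.0)    # +0.5 min
#' deltaCcs(204, 200)     # +2 percent
#' @export
deltaRt <- function(measured, reference) {
    if (any(measured <= 0) || any(reference <= 0))
        .inputError("retention times must be positive")
    measured - reference
}

#' @rdname deltaRt
#' @export
deltaCcs <- function(measured, reference) {
    if (any(measured <= 0) || any(reference <= 0))
        .inputError("CCS values must be positive")
    (measured - reference) / reference * 100
}

.asInterval <- function(x) {
    if (length(x) == 1L) {
        if (x <= 0) .inputError("a symmetric bound must be positive")
        c(-x, x)
    } else if (length(x) == 2L) {
        if (x[1L] >= x[2L]) .inputError("interval must be c(lo, hi) with lo < hi")
        as.numeric(x)
    } else .inputError("bound must be a single +-value or c(lo, hi)")
}

#' Continuous threshold-bounded score
#'
#' The continuous score of a deviation against a high/low confidence
#' threshold pair: deviations inside the high-confidence interval score
#' exactly 1; deviations outside the low-confidence interval score 0 (the
#' candidate is excluded); in between, the score decays linearly from 1
#' at the nearest high boundary to 0 at the low boundary on the same
#' side. The linear decay is the default `shape`; any strictly
#' decreasing map of the normalized overshoot `u` in `[0, 1]` to a score
#' `1 - f(u)` can be plugged in via `shape(u)` returning values in
#' `[0, 1]` with `shape(0) = 0`, `shape(1) = 1`.
#'
#' @param delta Numeric vector of deviations (same units as the bounds).
#' @param high,low High/low confidence threshold: either a single
#'   positive number `b` meaning `c(-b, b)`, or an interval `c(lo, hi)`.
#'   `high` must lie strictly inside `low`.
#' @param shape Optional overshoot-to-penalty function (default linear,
#'   `identity`).
#' @return Numeric scores in `[0, 1]`.
#' @examples
#' continuousScore(1.5, 2, 3)   # inside high: 1
#' continuousScore(2.5, 2, 3)   # halfway:     0.5
#' continuousScore(3.5, 2, 3)   # outside low: 0
#' @export
continuousScore <- function(delta, high, low, shape = identity) {
    high <- .asInterval(high)
    low <- .asInterval(low)
    if (!(low[1L] < high[1L] && high[2L] < low[2L]))
        .inputError("high-confidence interval must lie strictly inside the low-confidence interval")
    u <- numeric(length(delta))
    aboveHigh <- delta > high[2L]
    belowHigh <- delta < high[1L]
    u[aboveHigh] <- (delta[aboveHigh] - high[2L]) / (low[2L] - high[2L])
    u[belowHigh] <- (high[1L] - delta[belowHigh]) / (high[1L] - low[1L])
    u <- pmin(u, 1)
    score <- 1 - vapply(u, function(x) min(max(shape(x), 0), 1), numeric(1))
    score[delta <= low[1L] | delta >= low[2L]] <- 0
    score
}

#' Weighted multidimensional score fusion
#'
#' The multidimensional score is the weighted sum of the RT, CCS and MS2
#' scores. A missing MS2 score (fewer than the required monoisotopic
#' fragments, or no scorer output) contributes 0 with the weights left
#' unchanged - no renormalization - so that with the default weights a
#' candidate without MS2 can only reach the retention cutoff when both RT
#' and CCS scores are perfect.
#'
#' @param scoreRt,scoreCcs Numeric scores in `[0, 1]` (vectors recycle).
#' @param scoreMs2 Numeric scores in `[0, 1]`, `NA` when not estimable.
#' @param config A [ScoringConfig-class] supplying the weights.
#' @return Numeric fused scores in `[0, 1]`.
#' @examples
#' cfg <- scoringConfig()
#' fuseScores(1, 1, NA, cfg)   # exactly the 0.60 cutoff
#' fuseScores(1, 1, 1, cfg)    # 1
#' @export
fuseScores <- function(scoreRt, scoreCcs, scoreMs2 = NA_real_,
                       config = scoringConfig()) {
    sc <- cbind(rt = scoreRt, ccs = scoreCcs, ms2 = scoreMs2)
    if (any(sc < -1e-12 | sc > 1 + 1e-12, na.rm = TRUE))
        .inputError("scores must lie in [0, 1]")
    sc[is.na(sc[, "ms2"]), "ms2"] <- 0
    w <- config@weights
    as.numeric(sc[, "rt"] * w[["rt"]] + sc[, "ccs"] * w[["ccs"]] +
               sc[, "ms2"] * w[["ms2"]])
}
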