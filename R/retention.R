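# Retention-index handling and threshold calibration.
#
# Since n-alkanes evade APCI ionization, the working RI scale is the Fiehn
# scale (fatty acid methyl ester references); Kovats indices from
# literature are first mapped onto the Fiehn scale with a global linear
# fit over compounds carrying both indices, then converted to retention
# time with a piecewise-linear anchor calibration.

#' Fit a linear Kovats-to-Fiehn retention index map
#'
#' Least-squares fit of `fiehn = a * kovats + b` over compounds that carry
#' both index values. Both scales are near-affine transforms of elution
#' temperature over the relevant range, so a single global line suffices.
#'
#' @param kovats,fiehn Numeric vectors of paired index values (>= 2 pairs).
#' @return An object of class `riMap` with elements `slope` and
#'   `intercept`.
#' @examples
#' m <- riLinearMap(c(1000, 2000), c(1100, 2100))
#' kovatsToFiehn(1500, m)  # 1600
#' @export
riLinearMap <- function(kovats, fiehn) {
    if (length(kovats) != length(fiehn))
        .inputError("kovats and fiehn must have equal length")
    ok <- is.finite(kovats) & is.finite(fiehn)
    kovats <- kovats[ok]; fiehn <- fiehn[ok]
    if (length(kovats) < 2L)
        .inputError("at least 2 shared (kovats, fiehn) pairs are required")
    fit <- stats::lm.fit(cbind(1, kovats), fiehn)
    structure(list(intercept = unname(fit$coefficients[1L]),
                   slope = unname(fit$coefficients[2L])),
              class = "riMap")
}

#' @rdname riLinearMap
#' @param map An `riMap`.
#' @return `inverseRiMap()` returns the inverse `riMap` (Fiehn to Kovats).
#' @export
inverseRiMap <- function(map) {
    if (!inherits(map, "riMap")) .inputError("map must be an riMap")
    if (abs(map$slope) < .Machine$double.eps)
        .inputError("riMap with zero slope cannot be inverted")
    structure(list(intercept = -map$intercept / map$slope,
                   slope = 1 / map$slope), class = "riMap")
}

#' @rdname riLinearMap
#' @param ri Numeric vector of Kovats index values.
#' @return `kovatsToFiehn()` returns the mapped Fiehn index values.
#' @export
kovatsToFiehn <- function(ri, map) {
    if (!inherits(map, "riMap")) .inputError("map must be an riMap")
    map$intercept + map$slope * ri
}

#' Convert Fiehn retention indices to retention time
#'
#' Piecewise-linear interpolation between the bracketing calibration
#' anchors; outside the anchor range the terminal segment is extrapolated
#' and the value flagged via the `"extrapolated"` attribute.
#'
#' @param ri Numeric vector of Fiehn index values.
#' @param cal An [RICalibration-class] with `indexScale = "fiehn"`.
#' @return Numeric vector of retention times in minutes with a logical
#'   attribute `extrapolated` marking values outside the anchor range.
#' @examples
#' cal <- riCalibration(c(800, 1000), c(5, 10))
#' riToRt(900, cal)  # 7.5 min
#' @export
riToRt <- function(ri, cal) {
    if (!methods::is(cal, "RICalibration"))
        .inputError("cal must be an RICalibration")
    methods::validObject(cal)
    if (cal@indexScale != "fiehn")
        .inputError("riToRt requires a Fiehn-scale calibration; convert Kovats indices first")
    a <- cal@anchors
    n <- nrow(a)
    seg <- pmin(pmax(findInterval(ri, a$index), 1L), n - 1L)
    slope <- (a$rt[seg + 1L] - a$rt[seg]) / (a$index[seg + 1L] - a$index[seg])
    rt <- a$rt[seg] + slope * (ri - a$index[seg])
    attr(rt, "extrapolated") <- ri < a$index[1L] | ri > a$index[n]
    rt
}

#' Calibrate RT matching thresholds from reference residuals
#'
#' Given residuals between measured and reference retention times for a
#' set of calibration standards, the high-confidence interval is the mean
#' +- SD and the low-confidence interval the mean +- 2 SD. The intervals
#' are deliberately asymmetric about zero: a systematic bias of the
#' reference source is preserved rather than folded into the width.
#'
#' @param deltas Numeric vector of RT residuals (measured - reference), in
#'   minutes; at least 3 values.
#' @return List with elements `high` and `low`, each `c(lo, hi)` minutes.
#' @examples
#' calibrateRtThresholds(c(-0.4, 0.1, 0.2, 0.6))
#' @export
calibrateRtThresholds <- function(deltas) {
    deltas <- deltas[is.finite(deltas)]
    if (length(deltas) < 3L)
        .inputError("at least 3 RT residuals are required for calibration")
    mu <- mean(deltas)
    s <- stats::sd(deltas)
    if (s == 0)
        warning("degenerate RT calibration: zero spread, intervals collapse to a point")
    list(high = c(mu - s, mu + s), low = c(mu - 2 * s, mu + 2 * s))
}

.rtIntervals <- function(mu, s) {
    list(high = c(mu - s, mu + s), low = c(mu - 2 * s, mu + 2 * s))
}

#' Default calibrated thresholds
#'
#' The published calibration: CCS thresholds of +-2 / +-3 percent for
#' literature references (interlaboratory CCS reproducibility) and
#' +-5 / +-7 percent for model-predicted references (chosen to stay below
#' the smallest observed isomer CCS separation); RT intervals of mean +- SD
#' and mean +- 2 SD with residual summaries of 0.15 +- 0.69 min for
#' literature-converted references (n = 36) and 0.086 +- 1.13 min for
#' predicted references (n = 102). Measured RT references use the
#' literature intervals.
#'
#' @return A [ThresholdSet-class].
#' @examples
#' defaultThresholds()
#' @export
defaultThresholds <- function() {
    lit <- .rtIntervals(0.15, 0.69)
    pred <- .rtIntervals(0.086, 1.13)
    thresholdSet(ccsLiterature = c(2, 3), ccsPredicted = c(5, 7),
                 rtIntervals = list(measured = lit,
                                    literature_converted = lit,
                                    predicted = pred))
}
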