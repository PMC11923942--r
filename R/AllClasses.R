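# Central S4 data objects: thresholds, scoring configuration, suspect
# library, measured features, screening results, RI calibration, and the
# synthetic-bench configuration / ground truth.

.RT_SOURCES  <- c("measured", "literature_converted", "predicted")
.CCS_SOURCES <- c("literature", "predicted")

# ---------------------------------------------------------------- thresholds

#' ThresholdSet: calibrated high/low confidence matching thresholds
#'
#' Holds, per reference source, the high-confidence threshold (inside which
#' the continuous score is 1) and the low-confidence threshold (outside
#' which a candidate is excluded, score 0). CCS thresholds are symmetric
#' percentage bounds; RT thresholds are asymmetric intervals in minutes
#' (mean +- SD and mean +- 2 SD of calibration residuals, so the bias of
#' the reference source is preserved).
#'
#' @slot ccsLiterature Numeric of length 2, `c(high, low)` percent bounds
#'   for literature CCS references.
#' @slot ccsPredicted Numeric of length 2, `c(high, low)` percent bounds
#'   for model-predicted CCS references.
#' @slot rtIntervals Named list with one element per RT reference source
#'   (`measured`, `literature_converted`, `predicted`), each a list with
#'   `high` and `low` intervals `c(lo, hi)` in minutes, high strictly
#'   inside low.
#' @seealso [defaultThresholds()], [calibrateRtThresholds()]
#' @export
setClass("ThresholdSet",
         representation(ccsLiterature = "numeric",
                        ccsPredicted = "numeric",
                        rtIntervals = "list"))

setValidity("ThresholdSet", function(object) {
    msgs <- character(0)
    for (nm in c("ccsLiterature", "ccsPredicted")) {
        p <- slot(object, nm)
        if (length(p) != 2L || any(!is.finite(p)))
            msgs <- c(msgs, sprintf("%s must be two finite numbers", nm))
        else if (!(0 < p[1L] && p[1L] < p[2L]))
            msgs <- c(msgs, sprintf("%s must satisfy 0 < high < low", nm))
    }
    ri <- object@rtIntervals
    missing <- setdiff(.RT_SOURCES, names(ri))
    if (length(missing))
        msgs <- c(msgs, paste("missing RT intervals for source:",
                              paste(missing, collapse = ", ")))
    for (nm in intersect(names(ri), .RT_SOURCES)) {
        iv <- ri[[nm]]
        ok <- is.list(iv) && all(c("high", "low") %in% names(iv)) &&
            length(iv$high) == 2L && length(iv$low) == 2L &&
            all(is.finite(c(iv$high, iv$low)))
        if (!ok) {
            msgs <- c(msgs, sprintf("rtIntervals$%s must hold numeric high/low intervals", nm))
        } else if (!(iv$low[1L] < iv$high[1L] && iv$high[1L] < iv$high[2L] &&
                     iv$high[2L] < iv$low[2L])) {
            msgs <- c(msgs, sprintf(
                "rtIntervals$%s: high interval must lie strictly inside low", nm))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a ThresholdSet
#'
#' @param ccsLiterature,ccsPredicted `c(high, low)` percent bounds.
#' @param rtIntervals Named list of per-source RT intervals; see
#'   [ThresholdSet-class].
#' @return A [ThresholdSet-class] object.
#' @export
thresholdSet <- function(ccsLiterature = c(2, 3), ccsPredicted = c(5, 7),
                         rtIntervals) {
    methods::new("ThresholdSet",
                 ccsLiterature = as.numeric(ccsLiterature),
                 ccsPredicted = as.numeric(ccsPredicted),
                 rtIntervals = rtIntervals)
}

setMethod("show", "ThresholdSet", function(object) {
    cat("ThresholdSet\n")
    cat(sprintf("  CCS literature : +-%g%% / +-%g%%\n",
                object@ccsLiterature[1L], object@ccsLiterature[2L]))
    cat(sprintf("  CCS predicted  : +-%g%% / +-%g%%\n",
                object@ccsPredicted[1L], object@ccsPredicted[2L]))
    for (nm in names(object@rtIntervals)) {
        iv <- object@rtIntervals[[nm]]
        cat(sprintf("  RT %-20s: high [%.3f, %.3f], low [%.3f, %.3f] min\n",
                    nm, iv$high[1L], iv$high[2L], iv$low[1L], iv$low[2L]))
    }
    invisible(NULL)
})

# ------------------------------------------------------------------- config

#' ScoringConfig: weights, cutoff, gates and thresholds for screening
#'
#' @slot weights Named numeric `c(rt=, ccs=, ms2=)` summing to 1.
#' @slot cutoff Retention cutoff for the multidimensional score, in (0, 1].
#' @slot thresholds A [ThresholdSet-class].
#' @slot massTolPpm Mass-gate tolerance in ppm for ions at or above
#'   `massRuleBoundary`.
#' @slot massTolMda Mass-gate tolerance in mDa for ions below
#'   `massRuleBoundary`.
#' @slot massRuleBoundary m/z (Da) at which the ppm rule takes over from
#'   the mDa rule; the ppm rule applies at exactly the boundary.
#' @slot isotopeMaxGmDeviation Isotope gate: maximum geometric mean of
#'   relative intensity deviations, percent (strict `<`).
#' @slot minIsotopeIons Minimum number of matched non-base isotope ions.
#' @slot minMs2Fragments Minimum number of monoisotopic MS2 fragments for
#'   an MS2 similarity score to count.
#' @export
setClass("ScoringConfig",
         representation(weights = "numeric", cutoff = "numeric",
                        thresholds = "ThresholdSet",
                        massTolPpm = "numeric", massTolMda = "numeric",
                        massRuleBoundary = "numeric",
                        isotopeMaxGmDeviation = "numeric",
                        minIsotopeIons = "integer",
                        minMs2Fragments = "integer"))

setValidity("ScoringConfig", function(object) {
    msgs <- character(0)
    w <- object@weights
    if (!identical(sort(names(w)), sort(c("rt", "ccs", "ms2"))))
        msgs <- c(msgs, "weights must be named rt, ccs, ms2")
    else {
        if (any(w < 0)) msgs <- c(msgs, "weights must be non-negative")
        if (abs(sum(w) - 1) > 1e-8)
            msgs <- c(msgs, "weights must sum to 1")
    }
    if (!(length(object@cutoff) == 1L && object@cutoff > 0 &&
          object@cutoff <= 1))
        msgs <- c(msgs, "cutoff must be in (0, 1]")
    for (nm in c("massTolPpm", "massTolMda", "massRuleBoundary",
                 "isotopeMaxGmDeviation")) {
        v <- slot(object, nm)
        if (!(length(v) == 1L && is.finite(v) && v > 0))
            msgs <- c(msgs, sprintf("%s must be a positive number", nm))
    }
    if (object@minIsotopeIons < 0L)
        msgs <- c(msgs, "minIsotopeIons must be >= 0")
    if (object@minMs2Fragments < 1L)
        msgs <- c(msgs, "minMs2Fragments must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Construct a ScoringConfig
#'
#' Defaults are the published screening settings: weights 0.2/0.4/0.4 for
#' RT/CCS/MS2, cutoff 0.60, mass gate 5 ppm above 200 Da and 2 mDa below,
#' isotope geometric-mean deviation below 5 percent with at least one
#' isotope ion, and at least two monoisotopic fragments for MS2 scoring.
#'
#' @param weights Named numeric `c(rt=, ccs=, ms2=)` summing to 1.
#' @param cutoff Retention cutoff in (0, 1].
#' @param thresholds A [ThresholdSet-class]; defaults to
#'   [defaultThresholds()].
#' @param massTolPpm,massTolMda,massRuleBoundary Mass-gate rule.
#' @param isotopeMaxGmDeviation,minIsotopeIons Isotope-gate rule.
#' @param minMs2Fragments Minimum fragments for MS2 scoring.
#' @return A [ScoringConfig-class] object.
#' @examples
#' cfg <- scoringConfig()
#' cfg
#' @export
scoringConfig <- function(weights = c(rt = 0.2, ccs = 0.4, ms2 = 0.4),
                          cutoff = 0.60,
                          thresholds = defaultThresholds(),
                          massTolPpm = 5, massTolMda = 2,
                          massRuleBoundary = 200,
                          isotopeMaxGmDeviation = 5,
                          minIsotopeIons = 1L,
                          minMs2Fragments = 2L) {
    methods::new("ScoringConfig", weights = weights, cutoff = cutoff,
                 thresholds = thresholds,
                 massTolPpm = massTolPpm, massTolMda = massTolMda,
                 massRuleBoundary = massRuleBoundary,
                 isotopeMaxGmDeviation = isotopeMaxGmDeviation,
                 minIsotopeIons = as.integer(minIsotopeIons),
                 minMs2Fragments = as.integer(minMs2Fragments))
}

setMethod("show", "ScoringConfig", function(object) {
    w <- object@weights
    cat("ScoringConfig\n")
    cat(sprintf("  weights        : RT %.2f, CCS %.2f, MS2 %.2f\n",
                w[["rt"]], w[["ccs"]], w[["ms2"]]))
    cat(sprintf("  cutoff         : %.2f\n", object@cutoff))
    cat(sprintf("  mass gate      : <%g ppm (m/z >= %g Da), <%g mDa below\n",
                object@massTolPpm, object@massRuleBoundary,
                object@massTolMda))
    cat(sprintf("  isotope gate   : gm deviation < %g%%, >= %d isotope ion(s)\n",
                object@isotopeMaxGmDeviation, object@minIsotopeIons))
    cat(sprintf("  MS2 scoring    : >= %d monoisotopic fragments\n",
                object@minMs2Fragments))
    invisible(NULL)
})

# -------------------------------------------------------------- RI anchors

#' RICalibration: retention-index / retention-time anchor table
#'
#' Ordered reference-compound anchors mapping a retention-index scale
#' (Kovats n-alkanes or Fiehn fatty acid methyl esters) to retention time.
#'
#' @slot anchors `data.frame` with columns `index` and `rt` (minutes),
#'   strictly increasing in both.
#' @slot indexScale `"kovats"` or `"fiehn"`.
#' @export
setClass("RICalibration",
         representation(anchors = "data.frame", indexScale = "character"))

setValidity("RICalibration", function(object) {
    a <- object@anchors
    msgs <- character(0)
    if (!all(c("index", "rt") %in% names(a)))
        msgs <- c(msgs, "anchors must have columns index and rt")
    else {
        if (nrow(a) < 2L)
            msgs <- c(msgs, "at least 2 anchors are required")
        else if (any(diff(a$index) <= 0) || any(diff(a$rt) <= 0))
            msgs <- c(msgs, "anchors must be strictly increasing in index and rt")
    }
    if (!(length(object@indexScale) == 1L &&
          object@indexScale %in% c("kovats", "fiehn")))
        msgs <- c(msgs, "indexScale must be 'kovats' or 'fiehn'")
    if (length(msgs)) msgs else TRUE
})

#' Construct an RICalibration
#'
#' @param index Retention-index values (strictly increasing).
#' @param rt Retention times in minutes (strictly increasing).
#' @param indexScale `"fiehn"` (default) or `"kovats"`.
#' @return An [RICalibration-class] object.
#' @examples
#' riCalibration(c(800, 1000, 1200), c(5, 10, 14.5))
#' @export
riCalibration <- function(index, rt, indexScale = "fiehn") {
    methods::new("RICalibration",
                 anchors = data.frame(index = as.numeric(index),
                                      rt = as.numeric(rt)),
                 indexScale = indexScale)
}

setMethod("show", "RICalibration", function(object) {
    cat(sprintf("RICalibration (%s): %d anchors, index %g-%g, rt %.2f-%.2f min\n",
                object@indexScale, nrow(object@anchors),
                min(object@anchors$index), max(object@anchors$index),
                min(object@anchors$rt), max(object@anchors$rt)))
    invisible(NULL)
})

# ----------------------------------------------------------------- library

#' SuspectLibrary: the suspect screening library
#'
#' One row per suspect compound, with identity (id, CAS, InChIKey,
#' formula), theoretical adduct m/z for the radical cation and protonated
#' ion, a reference retention time tagged with its source, and a reference
#' collision cross section tagged with its source.
#'
#' @slot entries `data.frame` with columns `suspect_id`, `cas`,
#'   `inchikey`, `formula`, `mz_radical_cation`, `mz_protonated`,
#'   `rt_minutes`, `rt_source`, `ccs_a2`, `ccs_source`.
#' @seealso [readSuspectLibrary()], [suspectEntries()]
#' @export
setClass("SuspectLibrary", representation(entries = "data.frame"))

.LIBRARY_COLUMNS <- c("suspect_id", "cas", "inchikey", "formula",
                      "mz_radical_cation", "mz_protonated",
                      "rt_minutes", "rt_source", "ccs_a2", "ccs_source")

setValidity("SuspectLibrary", function(object) {
    e <- object@entries
    msgs <- character(0)
    missing <- setdiff(.LIBRARY_COLUMNS, names(e))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (nrow(e)) {
        if (anyDuplicated(e$suspect_id))
            msgs <- c(msgs, "suspect_id must be unique")
        if (any(!e$rt_source %in% .RT_SOURCES))
            msgs <- c(msgs, "rt_source must be measured, literature_converted or predicted")
        if (any(!e$ccs_source %in% .CCS_SOURCES))
            msgs <- c(msgs, "ccs_source must be literature or predicted")
        if (any(e$rt_minutes <= 0 | e$ccs_a2 <= 0))
            msgs <- c(msgs, "rt_minutes and ccs_a2 must be positive")
        mzr <- vapply(e$formula, function(f)
            adductMz(f, "radical_cation"), numeric(1))
        mzp <- vapply(e$formula, function(f)
            adductMz(f, "protonated"), numeric(1))
        if (any(abs(mzr - e$mz_radical_cation) > 1e-4) ||
            any(abs(mzp - e$mz_protonated) > 1e-4))
            msgs <- c(msgs, "adduct m/z inconsistent with formula (> 1e-4 Da)")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a SuspectLibrary from an entries table
#'
#' Missing adduct m/z columns are computed from the formula; missing
#' `cas`/`inchikey` columns are filled with `NA`.
#'
#' @param entries `data.frame`; see [SuspectLibrary-class].
#' @return A [SuspectLibrary-class] object.
#' @export
suspectLibrary <- function(entries) {
    entries <- as.data.frame(entries)
    for (nm in c("cas", "inchikey"))
        if (!nm %in% names(entries)) entries[[nm]] <- NA_character_
    if (!"mz_radical_cation" %in% names(entries))
        entries$mz_radical_cation <- vapply(entries$formula, function(f)
            adductMz(f, "radical_cation"), numeric(1))
    if (!"mz_protonated" %in% names(entries))
        entries$mz_protonated <- vapply(entries$formula, function(f)
            adductMz(f, "protonated"), numeric(1))
    entries <- entries[, .LIBRARY_COLUMNS, drop = FALSE]
    rownames(entries) <- NULL
    methods::new("SuspectLibrary", entries = entries)
}

setMethod("show", "SuspectLibrary", function(object) {
    e <- object@entries
    cat(sprintf("SuspectLibrary with %d entries\n", nrow(e)))
    if (nrow(e)) {
        cat(sprintf("  rt_source : %s\n",
                    paste(sprintf("%s (%d)", names(table(e$rt_source)),
                                  table(e$rt_source)), collapse = ", ")))
        cat(sprintf("  ccs_source: %s\n",
                    paste(sprintf("%s (%d)", names(table(e$ccs_source)),
                                  table(e$ccs_source)), collapse = ", ")))
    }
    invisible(NULL)
})

# ---------------------------------------------------------------- features

#' FeatureSet: measured, deconvoluted features
#'
#' One row per aligned feature with m/z of the base isotopologue, measured
#' retention time and collision cross section, intensity, the measured
#' isotope envelope and any MS2 fragments (both as list columns of
#' two-column `data.frame`s).
#'
#' @slot features `data.frame` with columns `feature_id`, `mz`,
#'   `rt_minutes`, `ccs_a2`, `intensity`, and list columns
#'   `isotope_envelope` (`mz`, `relint`) and `ms2_fragments`
#'   (`mz`, `intensity`).
#' @seealso [readFeatureTable()], [features()]
#' @export
setClass("FeatureSet", representation(features = "data.frame"))

.FEATURE_COLUMNS <- c("feature_id", "mz", "rt_minutes", "ccs_a2",
                      "intensity", "isotope_envelope", "ms2_fragments")

setValidity("FeatureSet", function(object) {
    f <- object@features
    msgs <- character(0)
    missing <- setdiff(.FEATURE_COLUMNS, names(f))
    if (length(missing))
        return(paste("missing columns:", paste(missing, collapse = ", ")))
    if (nrow(f)) {
        if (anyDuplicated(f$feature_id))
            msgs <- c(msgs, "feature_id must be unique")
        if (any(f$mz <= 0 | f$rt_minutes <= 0 | f$ccs_a2 <= 0 |
                f$intensity <= 0))
            msgs <- c(msgs, "mz, rt_minutes, ccs_a2 and intensity must be positive")
        badEnv <- vapply(f$isotope_envelope, function(e) {
            nrow(e) > 0L && !any(abs(e$relint - 100) < 1e-9)
        }, logical(1))
        if (any(badEnv))
            msgs <- c(msgs, "non-empty isotope envelopes must contain a base peak at 100%")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a FeatureSet
#'
#' @param features `data.frame`; see [FeatureSet-class]. Missing envelope /
#'   fragment list columns are filled with empty tables.
#' @return A [FeatureSet-class] object.
#' @export
featureSet <- function(features) {
    features <- as.data.frame(features)
    n <- nrow(features)
    if (!"isotope_envelope" %in% names(features))
        features$isotope_envelope <- I(replicate(n, .emptyEnvelope(),
                                                 simplify = FALSE))
    if (!"ms2_fragments" %in% names(features))
        features$ms2_fragments <- I(replicate(n, .emptyFragments(),
                                              simplify = FALSE))
    features <- features[, .FEATURE_COLUMNS, drop = FALSE]
    rownames(features) <- NULL
    methods::new("FeatureSet", features = features)
}

.emptyEnvelope <- function() data.frame(mz = numeric(0), relint = numeric(0))
.emptyFragments <- function() data.frame(mz = numeric(0),
                                         intensity = numeric(0))

setMethod("show", "FeatureSet", function(object) {
    f <- object@features
    nFrag <- vapply(f$ms2_fragments, nrow, integer(1))
    cat(sprintf("FeatureSet with %d features (%d with >= 1 MS2 fragment)\n",
                nrow(f), sum(nFrag > 0L)))
    invisible(NULL)
})

# ------------------------------------------------------------------ result

#' ScreeningResult: scored candidates and stage-wise hit counts
#'
#' @slot candidates `data.frame`, one row per (feature, suspect) candidate
#'   that passed the mandatory exact-mass and isotope-pattern gates, with
#'   delta values, per-dimension scores, the fused multidimensional score
#'   and retention flags.
#' @slot stageCounts Named integer vector with the four workflow stages:
#'   `ms1_rt` (mass + isotope + RT match), `ms1_rt_ccs` (plus CCS match),
#'   `above_cutoff` (multidimensional score at or above the cutoff) and
#'   `best_retained` (highest-scoring candidate per suspect).
#' @slot config The [ScoringConfig-class] used.
#' @export
setClass("ScreeningResult",
         representation(candidates = "data.frame", stageCounts = "integer",
                        config = "ScoringConfig"))

.STAGE_NAMES <- c("ms1_rt", "ms1_rt_ccs", "above_cutoff", "best_retained")

setValidity("ScreeningResult", function(object) {
    msgs <- character(0)
    sc <- object@stageCounts
    if (!identical(names(sc), .STAGE_NAMES))
        msgs <- c(msgs, paste("stageCounts must be named",
                              paste(.STAGE_NAMES, collapse = ", ")))
    else if (any(diff(sc) > 0L))
        msgs <- c(msgs, "stage counts must be non-increasing")
    cand <- object@candidates
    if (nrow(cand)) {
        sccol <- cand$multidimensional_score
        if (any(sccol < -1e-9 | sccol > 1 + 1e-9))
            msgs <- c(msgs, "multidimensional scores must lie in [0, 1]")
        if (any(cand$retained &
                sccol < object@config@cutoff - 1e-9))
            msgs <- c(msgs, "retained candidates must score at or above the cutoff")
    }
    if (length(msgs)) msgs else TRUE
})

setMethod("show", "ScreeningResult", function(object) {
    sc <- object@stageCounts
    cat("ScreeningResult\n")
    cat(sprintf("  candidates passing MS1 gates : %d\n",
                nrow(object@candidates)))
    cat(sprintf("  MS1 + RT match               : %d\n", sc[["ms1_rt"]]))
    cat(sprintf("  MS1 + RT + CCS match         : %d\n", sc[["ms1_rt_ccs"]]))
    cat(sprintf("  score >= cutoff              : %d\n", sc[["above_cutoff"]]))
    cat(sprintf("  best retained per suspect    : %d\n",
                sc[["best_retained"]]))
    invisible(NULL)
})

# --------------------------------------------------------- synthetic bench

#' SimulationConfig: settings for the ground-truthed synthetic bench
#'
#' Defaults emulate the dispersion observed for real standards: RT noise
#' SD 0.69 min around a +0.15 min conversion bias (literature-converted
#' references), CCS noise SD 2 percent (interlaboratory reproducibility),
#' 1 ppm mass noise, 2 percent isotope intensity noise and MS2 similarity
#' scores of 0.724 +- 0.180 for true candidates.
#'
#' @slot nSuspects Number of library suspects.
#' @slot fractionPresent Fraction of suspects planted as features.
#' @slot isomerDecoyRate Fraction of planted suspects that also get an
#'   isomeric decoy library entry (same formula, CCS shifted by 3-5
#'   percent, RT shifted by 0.5-2 min).
#' @slot rtNoiseMean,rtNoiseSd RT deviation mean/SD in minutes.
#' @slot ccsNoiseSd CCS deviation SD in percent.
#' @slot massNoiseSdPpm m/z noise SD in ppm.
#' @slot isotopeNoiseSd Isotope relative-intensity noise SD in percent.
#' @slot ms2TrueScore,ms2FalseScore `c(mean, sd)` of simulated MS2
#'   similarity scores for true and decoy pairings (truncated to [0, 1]).
#' @slot ms2MissingRate Fraction of planted features without usable MS2.
#' @slot seed Integer seed driving all randomness.
#' @export
setClass("SimulationConfig",
         representation(nSuspects = "integer", fractionPresent = "numeric",
                        isomerDecoyRate = "numeric",
                        rtNoiseMean = "numeric", rtNoiseSd = "numeric",
                        ccsNoiseSd = "numeric", massNoiseSdPpm = "numeric",
                        isotopeNoiseSd = "numeric",
                        ms2TrueScore = "numeric", ms2FalseScore = "numeric",
                        ms2MissingRate = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msgs <- character(0)
    for (nm in c("fractionPresent", "isomerDecoyRate", "ms2MissingRate")) {
        v <- slot(object, nm)
        if (!(length(v) == 1L && v >= 0 && v <= 1))
            msgs <- c(msgs, sprintf("%s must be in [0, 1]", nm))
    }
    for (nm in c("rtNoiseSd", "ccsNoiseSd", "massNoiseSdPpm",
                 "isotopeNoiseSd")) {
        v <- slot(object, nm)
        if (!(length(v) == 1L && v >= 0))
            msgs <- c(msgs, sprintf("%s must be >= 0", nm))
    }
    for (nm in c("ms2TrueScore", "ms2FalseScore")) {
        v <- slot(object, nm)
        if (!(length(v) == 2L && v[1L] >= 0 && v[1L] <= 1 && v[2L] >= 0))
            msgs <- c(msgs, sprintf("%s must be c(mean in [0,1], sd >= 0)", nm))
    }
    if (object@nSuspects < 1L)
        msgs <- c(msgs, "nSuspects must be >= 1")
    if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nSuspects,fractionPresent,isomerDecoyRate,rtNoiseMean,rtNoiseSd
#'   See [SimulationConfig-class].
#' @param ccsNoiseSd,massNoiseSdPpm,isotopeNoiseSd,ms2TrueScore
#'   See [SimulationConfig-class].
#' @param ms2FalseScore,ms2MissingRate,seed See [SimulationConfig-class].
#' @return A [SimulationConfig-class] object.
#' @examples
#' simulationConfig(nSuspects = 50, seed = 7)
#' @export
simulationConfig <- function(nSuspects = 200L, fractionPresent = 0.5,
                             isomerDecoyRate = 0,
                             rtNoiseMean = 0.15, rtNoiseSd = 0.69,
                             ccsNoiseSd = 2, massNoiseSdPpm = 1,
                             isotopeNoiseSd = 2,
                             ms2TrueScore = c(0.724, 0.180),
                             ms2FalseScore = c(0.5, 0.2),
                             ms2MissingRate = 0.2, seed = 1L) {
    methods::new("SimulationConfig",
                 nSuspects = as.integer(nSuspects),
                 fractionPresent = fractionPresent,
                 isomerDecoyRate = isomerDecoyRate,
                 rtNoiseMean = rtNoiseMean, rtNoiseSd = rtNoiseSd,
                 ccsNoiseSd = ccsNoiseSd, massNoiseSdPpm = massNoiseSdPpm,
                 isotopeNoiseSd = isotopeNoiseSd,
                 ms2TrueScore = ms2TrueScore, ms2FalseScore = ms2FalseScore,
                 ms2MissingRate = ms2MissingRate, seed = as.integer(seed))
}

#' GroundTruth: planted identities and decoy bookkeeping
#'
#' @slot planted Named character vector mapping `feature_id` to the true
#'   `suspect_id` of the planted compound.
#' @slot decoyIsomers Named character vector mapping a true `suspect_id`
#'   to its isomeric decoy `suspect_id`.
#' @export
setClass("GroundTruth",
         representation(planted = "character", decoyIsomers = "character"))

#' Construct a GroundTruth
#'
#' @param planted,decoyIsomers Named character vectors; see
#'   [GroundTruth-class].
#' @return A [GroundTruth-class] object.
#' @export
groundTruth <- function(planted = character(0),
                        decoyIsomers = character(0)) {
    methods::new("GroundTruth", planted = planted,
                 decoyIsomers = decoyIsomers)
}

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d planted features, %d isomeric decoys\n",
                length(object@planted), length(object@decoyIsomers)))
    invisible(NULL)
})

# --------------------------------------------------------------- accessors

#' Accessors for the central data objects
#'
#' `suspectEntries()` returns the library entry table, `features()` the
#' measured-feature table, `candidates()` the candidate table of a
#' screening result and `stageCounts()` its four stage-wise hit counts.
#'
#' @param object A [SuspectLibrary-class], [FeatureSet-class] or
#'   [ScreeningResult-class].
#' @return A `data.frame` (or named integer vector for `stageCounts()`).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("suspectEntries", function(object)
    standardGeneric("suspectEntries"))

#' @rdname accessors
#' @export
setMethod("suspectEntries", "SuspectLibrary", function(object)
    object@entries)

#' @rdname accessors
#' @export
setGeneric("features", function(object) standardGeneric("features"))

#' @rdname accessors
#' @export
setMethod("features", "FeatureSet", function(object) object@features)

#' @rdname accessors
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))

#' @rdname accessors
#' @export
setMethod("candidates", "ScreeningResult", function(object)
    object@candidates)

#' @rdname accessors
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname accessors
#' @export
setMethod("stageCounts", "ScreeningResult", function(object)
    object@stageCounts)

#' @rdname accessors
#' @export
setGeneric("scoringThresholds", function(object)
    standardGeneric("scoringThresholds"))

#' @rdname accessors
#' @export
setMethod("scoringThresholds", "ScoringConfig", function(object)
    object@thresholds)

#' @param x A [SuspectLibrary-class] or [FeatureSet-class].
#' @rdname accessors
#' @export
setMethod("length", "SuspectLibrary", function(x) nrow(x@entries))

#' @rdname accessors
#' @export
setMethod("length", "FeatureSet", function(x) nrow(x@features))
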