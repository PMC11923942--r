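# The end-to-end screening workflow: MS1 gating, continuous RT/CCS
# scoring, MS2 fusion, cutoff, and best-candidate retention per suspect.

.rtIntervalsFor <- function(thresholds, source) {
    thresholds@rtIntervals[[source]]
}

.ccsBoundsFor <- function(thresholds, source) {
    if (source == "literature") thresholds@ccsLiterature
    else thresholds@ccsPredicted
}

.emptyCandidates <- function() {
    data.frame(feature_id = character(0), suspect_id = character(0),
               adduct = character(0), theoretical_mz = numeric(0),
               measured_mz = numeric(0), mass_error_ppm = numeric(0),
               mass_error_mda = numeric(0),
               isotope_gm_deviation = numeric(0),
               isotope_bypass = logical(0), delta_rt = numeric(0),
               delta_ccs = numeric(0), rt_pass = logical(0),
               ccs_pass = logical(0), score_rt = numeric(0),
               score_ccs = numeric(0), score_ms2 = numeric(0),
               multidimensional_score = numeric(0),
               above_cutoff = logical(0), retained = logical(0),
               stringsAsFactors = FALSE)
}

#' Screen measured features against a suspect library
#'
#' For every (feature, suspect, adduct) triple whose theoretical m/z lies
#' near the feature m/z, the mandatory exact-mass and isotope-pattern
#' gates are applied; for pairs passing both (keeping the best adduct per
#' pair, by smaller absolute ppm error), signed RT and CCS differences
#' are computed and scored continuously against the source-matched
#' thresholds. Candidates whose RT or CCS difference falls outside the
#' low-confidence threshold are excluded (score 0). An MS2 similarity
#' score is attached when one was supplied for the pair and the feature
#' carries at least `minMs2Fragments` fragments; the weighted
#' multidimensional score is then fused and candidates at or above the
#' cutoff are marked, with the highest-scoring candidate per suspect
#' retained.
#'
#' Stage-wise hit counts mirror the four workflow stages: MS1 + RT match;
#' MS1 + RT + CCS match; multidimensional score at or above the cutoff;
#' and best retained per suspect.
#'
#' @param featureSet A [FeatureSet-class] (or its `features()` table).
#' @param library A [SuspectLibrary-class] (or its entry table).
#' @param ms2Scores Optional `data.frame` (`feature_id`, `suspect_id`,
#'   `score`) as from [readMs2Scores()]; `NULL` means no MS2 scores.
#' @param config A [ScoringConfig-class].
#' @return A [ScreeningResult-class].
#' @seealso [rankCandidates()], [evaluateScreening()]
#' @export
screenFeatures <- function(featureSet, library, ms2Scores = NULL,
                           config = scoringConfig()) {
    feat <- if (methods::is(featureSet, "FeatureSet"))
        features(featureSet) else featureSet
    lib <- if (methods::is(library, "SuspectLibrary"))
        suspectEntries(library) else library
    if (nrow(feat) == 0L || nrow(lib) == 0L) {
        warning("screenFeatures: empty feature list or library; empty result")
        return(methods::new("ScreeningResult",
                            candidates = .emptyCandidates(),
                            stageCounts = stats::setNames(integer(4),
                                                          .STAGE_NAMES),
                            config = config))
    }

    # long adduct table, sorted by theoretical m/z for windowed joining
    add <- rbind(
        data.frame(lib_row = seq_len(nrow(lib)), adduct = "radical_cation",
                   theo = lib$mz_radical_cation),
        data.frame(lib_row = seq_len(nrow(lib)), adduct = "protonated",
                   theo = lib$mz_protonated))
    add <- add[order(add$theo), ]
    # coarse +-0.02 Da window comfortably covers both mass rules
    win <- max(0.02, config@massTolPpm * 1e-6 * max(add$theo))
    lo <- findInterval(feat$mz - win, add$theo) + 1L
    hi <- findInterval(feat$mz + win, add$theo)
    nper <- pmax(hi - lo + 1L, 0L)
    if (sum(nper) == 0L)
        return(methods::new("ScreeningResult",
                            candidates = .emptyCandidates(),
                            stageCounts = stats::setNames(integer(4),
                                                          .STAGE_NAMES),
                            config = config))
    fidx <- rep(seq_len(nrow(feat)), nper)
    aidx <- sequence(nper) + rep(lo - 1L, nper)

    gate <- massGate(feat$mz[fidx], add$theo[aidx], config)
    ok <- gate$pass
    fidx <- fidx[ok]; aidx <- aidx[ok]
    ppm <- gate$ppm[ok]; mda <- gate$mda[ok]

    # isotope gate, with theoretical patterns cached per formula + adduct
    patternCache <- new.env(parent = emptyenv())
    theoreticalPattern <- function(formula, adduct) {
        key <- paste(formula, adduct)
        if (!is.null(patternCache[[key]])) return(patternCache[[key]])
        patternCache[[key]] <- isotopePattern(formula, adduct)
        patternCache[[key]]
    }
    nPairs <- length(fidx)
    isoPass <- logical(nPairs)
    isoDev <- rep(NA_real_, nPairs)
    isoBypass <- logical(nPairs)
    for (k in seq_len(nPairs)) {
        theory <- theoreticalPattern(lib$formula[add$lib_row[aidx[k]]],
                                     add$adduct[aidx[k]])
        g <- isotopeGate(feat$isotope_envelope[[fidx[k]]], theory, config)
        isoPass[k] <- g$pass
        isoDev[k] <- g$gmDeviation
        isoBypass[k] <- g$bypass
    }
    keep <- isoPass
    fidx <- fidx[keep]; aidx <- aidx[keep]
    ppm <- ppm[keep]; mda <- mda[keep]
    isoDev <- isoDev[keep]; isoBypass <- isoBypass[keep]

    cand <- data.frame(
        feature_id = feat$feature_id[fidx],
        suspect_id = lib$suspect_id[add$lib_row[aidx]],
        adduct = add$adduct[aidx],
        theoretical_mz = add$theo[aidx],
        measured_mz = feat$mz[fidx],
        mass_error_ppm = ppm, mass_error_mda = mda,
        isotope_gm_deviation = isoDev, isotope_bypass = isoBypass,
        stringsAsFactors = FALSE)
    cand$.f <- fidx
    cand$.l <- add$lib_row[aidx]

    # best adduct per (feature, suspect): smaller |ppm| wins
    if (nrow(cand)) {
        ord <- order(cand$feature_id, cand$suspect_id,
                     abs(cand$mass_error_ppm))
        cand <- cand[ord, ]
        cand <- cand[!duplicated(paste(cand$feature_id, cand$suspect_id)), ]
    }

    thr <- config@thresholds
    n <- nrow(cand)
    cand$delta_rt <- deltaRt(feat$rt_minutes[cand$.f],
                             lib$rt_minutes[cand$.l])
    cand$delta_ccs <- deltaCcs(feat$ccs_a2[cand$.f], lib$ccs_a2[cand$.l])
    cand$rt_pass <- logical(n)
    cand$ccs_pass <- logical(n)
    cand$score_rt <- numeric(n)
    cand$score_ccs <- numeric(n)
    for (k in seq_len(n)) {
        iv <- .rtIntervalsFor(thr, lib$rt_source[cand$.l[k]])
        cand$score_rt[k] <- continuousScore(cand$delta_rt[k], iv$high,
                                            iv$low)
        cand$rt_pass[k] <- cand$delta_rt[k] > iv$low[1L] &&
            cand$delta_rt[k] < iv$low[2L]
        cb <- .ccsBoundsFor(thr, lib$ccs_source[cand$.l[k]])
        cand$score_ccs[k] <- continuousScore(cand$delta_ccs[k], cb[1L],
                                             cb[2L])
        cand$ccs_pass[k] <- abs(cand$delta_ccs[k]) < cb[2L]
    }

    # attach MS2 scores where available and estimable
    nFrag <- vapply(feat$ms2_fragments, nrow, integer(1))
    cand$score_ms2 <- NA_real_
    if (!is.null(ms2Scores) && nrow(ms2Scores)) {
        key <- paste(ms2Scores$feature_id, ms2Scores$suspect_id, sep = "\r")
        idx <- match(paste(cand$feature_id, cand$suspect_id, sep = "\r"),
                     key)
        scorable <- nFrag[cand$.f] >= config@minMs2Fragments
        cand$score_ms2 <- ifelse(!is.na(idx) & scorable,
                                 ms2Scores$score[idx], NA_real_)
    }

    cand$multidimensional_score <- ifelse(
        cand$rt_pass & cand$ccs_pass,
        fuseScores(cand$score_rt, cand$score_ccs, cand$score_ms2, config),
        0)
    cand$above_cutoff <- cand$rt_pass & cand$ccs_pass &
        cand$multidimensional_score >= config@cutoff - 1e-9

    # best retained candidate per suspect (deterministic tie-break)
    cand$retained <- FALSE
    if (any(cand$above_cutoff)) {
        sel <- which(cand$above_cutoff)
        ord <- sel[order(cand$suspect_id[sel],
                         -cand$multidimensional_score[sel],
                         abs(cand$delta_ccs[sel]),
                         abs(cand$mass_error_ppm[sel]),
                         cand$feature_id[sel])]
        best <- ord[!duplicated(cand$suspect_id[ord])]
        cand$retained[best] <- TRUE
    }

    stage <- stats::setNames(c(sum(cand$rt_pass),
                               sum(cand$rt_pass & cand$ccs_pass),
                               sum(cand$above_cutoff),
                               sum(cand$retained)), .STAGE_NAMES)
    cand$.f <- NULL
    cand$.l <- NULL
    rownames(cand) <- NULL
    methods::new("ScreeningResult", candidates = cand,
                 stageCounts = as.integer(stage) |>
                     stats::setNames(.STAGE_NAMES),
                 config = config)
}

#' Rank screening candidates
#'
#' Orders the candidate table by descending multidimensional score, with
#' deterministic tie-breaking by smaller absolute CCS difference, then
#' smaller absolute ppm mass error, then lexicographic suspect id.
#'
#' @param result A [ScreeningResult-class] (or its candidate table).
#' @param retainedOnly If `TRUE`, rank only the retained best-per-suspect
#'   candidates.
#' @return The reordered candidate `data.frame` with a `rank` column.
#' @export
rankCandidates <- function(result, retainedOnly = FALSE) {
    cand <- if (methods::is(result, "ScreeningResult"))
        candidates(result) else result
    if (retainedOnly) cand <- cand[cand$retained, , drop = FALSE]
    if (nrow(cand)) {
        ord <- order(-cand$multidimensional_score, abs(cand$delta_ccs),
                     abs(cand$mass_error_ppm), cand$suspect_id)
        cand <- cand[ord, , drop = FALSE]
        rownames(cand) <- NULL
    }
    cand$rank <- seq_len(nrow(cand))
    cand
}

# ------------------------------------------------------------- result I/O

#' Write / read a screening result as delimited text
#'
#' `writeScreeningResult()` writes `candidates.csv` (one row per
#' candidate with all deltas, scores and flags) and `stage_counts.csv`
#' into `dir`; `readScreeningResult()` reads them back. The scoring
#' configuration is archived alongside as `scoring_config.yaml`.
#'
#' @param result A [ScreeningResult-class].
#' @param dir Output directory (created if needed).
#' @return `writeScreeningResult()` returns `dir` invisibly;
#'   `readScreeningResult()` returns a [ScreeningResult-class].
#' @export
writeScreeningResult <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    cand <- candidates(result)
    num <- vapply(cand, is.numeric, logical(1))
    out <- cand
    for (nm in names(cand)[num]) out[[nm]] <- .num2str(cand[[nm]])
    utils::write.csv(out, file.path(dir, "candidates.csv"),
                     row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    utils::write.csv(data.frame(stage = names(stageCounts(result)),
                                hits = as.integer(stageCounts(result))),
                     file.path(dir, "stage_counts.csv"),
                     row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    writeScoringConfig(result@config, file.path(dir, "scoring_config.yaml"))
    invisible(dir)
}

#' @rdname writeScreeningResult
#' @export
readScreeningResult <- function(dir) {
    candPath <- file.path(dir, "candidates.csv")
    stagePath <- file.path(dir, "stage_counts.csv")
    if (!file.exists(candPath) || !file.exists(stagePath))
        .inputError(sprintf(
            "%s does not contain candidates.csv and stage_counts.csv", dir))
    cand <- utils::read.csv(candPath, stringsAsFactors = FALSE)
    if (nrow(cand) == 0L) cand <- .emptyCandidates()
    cand$feature_id <- as.character(cand$feature_id)
    cand$suspect_id <- as.character(cand$suspect_id)
    stage <- utils::read.csv(stagePath, stringsAsFactors = FALSE)
    cfgPath <- file.path(dir, "scoring_config.yaml")
    cfg <- if (file.exists(cfgPath)) readScoringConfig(cfgPath)
           else scoringConfig()
    methods::new("ScreeningResult", candidates = cand,
                 stageCounts = stats::setNames(as.integer(stage$hits),
                                               stage$stage),
                 config = cfg)
}

# ------------------------------------------------------------- config I/O

#' Round-trippable scoring configuration file
#'
#' The full [ScoringConfig-class] (weights, cutoff, mass/isotope gates
#' and all thresholds) serialized as YAML, the single source of scoring
#' settings for the command-line workflow.
#'
#' @param config A [ScoringConfig-class].
#' @param path File path.
#' @return `writeScoringConfig()` returns `path` invisibly;
#'   `readScoringConfig()` returns a [ScoringConfig-class].
#' @export
writeScoringConfig <- function(config, path) {
    thr <- config@thresholds
    obj <- list(
        weights = as.list(config@weights),
        cutoff = config@cutoff,
        mass_tol_ppm = config@massTolPpm,
        mass_tol_mda = config@massTolMda,
        mass_rule_boundary = config@massRuleBoundary,
        isotope_max_gm_deviation = config@isotopeMaxGmDeviation,
        min_isotope_ions = config@minIsotopeIons,
        min_ms2_fragments = config@minMs2Fragments,
        thresholds = list(
            ccs_literature = as.numeric(thr@ccsLiterature),
            ccs_predicted = as.numeric(thr@ccsPredicted),
            rt_intervals = lapply(thr@rtIntervals, function(iv)
                list(high = as.numeric(iv$high),
                     low = as.numeric(iv$low)))))
    yaml::write_yaml(obj, path, precision = 15L)
    invisible(path)
}

#' @rdname writeScoringConfig
#' @export
readScoringConfig <- function(path) {
    if (!file.exists(path))
        .inputError(sprintf("config file not found: %s", path))
    obj <- yaml::read_yaml(path)
    thr <- thresholdSet(
        ccsLiterature = as.numeric(obj$thresholds$ccs_literature),
        ccsPredicted = as.numeric(obj$thresholds$ccs_predicted),
        rtIntervals = lapply(obj$thresholds$rt_intervals, function(iv)
            list(high = as.numeric(iv$high), low = as.numeric(iv$low))))
    scoringConfig(weights = unlist(obj$weights)[c("rt", "ccs", "ms2")],
                  cutoff = obj$cutoff, thresholds = thr,
                  massTolPpm = obj$mass_tol_ppm,
                  massTolMda = obj$mass_tol_mda,
                  massRuleBoundary = obj$mass_rule_boundary,
                  isotopeMaxGmDeviation = obj$isotope_max_gm_deviation,
                  minIsotopeIons = obj$min_isotope_ions,
                  minMs2Fragments = obj$min_ms2_fragments)
}
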