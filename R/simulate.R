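# Ground-truthed synthetic datasets emulating the fortified-sediment
# validation, and workflow evaluation against the planted truth.

# truncated-normal draw on [0, 1] (simple clamping; the simulated MS2
# similarity scale is bounded by construction)
.truncScore <- function(n, meansd) {
    pmin(pmax(stats::rnorm(n, meansd[1L], meansd[2L]), 0), 1)
}

# random halogen-rich formulas with loosely valence-plausible H counts
.randomFormulas <- function(n) {
    out <- character(0)
    while (length(out) < n) {
        m <- n - length(out)
        nC <- sample(6:24, m, replace = TRUE)
        nCl <- sample(0:6, m, replace = TRUE)
        nBr <- sample(0:3, m, replace = TRUE)
        none <- nCl + nBr == 0L
        nCl[none] <- sample(1:6, sum(none), replace = TRUE)
        hMax <- pmax(2L * nC + 2L - nCl - nBr, 0L)
        nH <- pmax(hMax - 2L * sample(0:7, m, replace = TRUE), 0L)
        f <- vapply(seq_len(m), function(i) {
            counts <- c(C = nC[i], H = nH[i], Br = nBr[i], Cl = nCl[i])
            formulaToString(counts[counts > 0L])
        }, character(1))
        out <- unique(c(out, f))
    }
    out[seq_len(n)]
}

#' Simulate a ground-truthed screening dataset
#'
#' Generates a suspect library of unique random halogen-rich formulas
#' with plausible retention times (uniform over the 5-35 min window) and
#' collision cross sections (a power law in ion mass with 5 percent
#' compound-to-compound scatter), plants a configurable fraction of them
#' as measured features with Gaussian noise on m/z (relative, ppm), RT
#' (absolute, minutes, around the reference-source bias), CCS (relative,
#' percent) and isotope intensities, and simulates MS2 similarity scores
#' directly as truncated-Gaussian fractions. At `isomerDecoyRate`, a
#' planted suspect additionally gets an isomeric decoy library entry:
#' same formula, CCS shifted by 3-5 percent and RT shifted by 0.5-2 min
#' in a random direction, with its own (lower) simulated MS2 score
#' against the planted feature. All randomness derives from the config
#' seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List with elements `library` ([SuspectLibrary-class]),
#'   `features` ([FeatureSet-class]), `ms2Scores` (`data.frame`) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateDataset(simulationConfig(nSuspects = 20, seed = 3))
#' sim$library
#' @export
simulateDataset <- function(config = simulationConfig()) {
    methods::validObject(config)
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    set.seed(config@seed)

    n <- config@nSuspects
    formulas <- .randomFormulas(n)
    mono <- vapply(formulas, monoisotopicMass, numeric(1))
    entries <- data.frame(
        suspect_id = sprintf("S%04d", seq_len(n)),
        cas = NA_character_,
        inchikey = sprintf("SYNTHKEY%04d", seq_len(n)),
        formula = formulas,
        rt_minutes = stats::runif(n, 5, 35),
        rt_source = "literature_converted",
        ccs_a2 = 8.6 * mono^0.52 * (1 + stats::rnorm(n, 0, 0.05)),
        ccs_source = "literature",
        stringsAsFactors = FALSE)

    nPresent <- round(config@fractionPresent * n)
    planted <- if (nPresent > 0L) sort(sample.int(n, nPresent)) else
        integer(0)

    decoys <- NULL
    decoyMap <- character(0)
    if (config@isomerDecoyRate > 0 && length(planted)) {
        nDecoy <- round(config@isomerDecoyRate * length(planted))
        if (nDecoy > 0L) {
            which <- sort(sample(planted, nDecoy))
            decoys <- entries[which, , drop = FALSE]
            decoys$suspect_id <- paste0(entries$suspect_id[which], "_iso")
            decoys$inchikey <- paste0(entries$inchikey[which], "ISO")
            ccsShift <- stats::runif(nDecoy, 3, 5) / 100 *
                sample(c(-1, 1), nDecoy, replace = TRUE)
            rtShift <- stats::runif(nDecoy, 0.5, 2) *
                sample(c(-1, 1), nDecoy, replace = TRUE)
            decoys$ccs_a2 <- decoys$ccs_a2 * (1 + ccsShift)
            decoys$rt_minutes <- pmax(decoys$rt_minutes + rtShift, 0.5)
            decoyMap <- stats::setNames(decoys$suspect_id,
                                        entries$suspect_id[which])
        }
    }
    lib <- suspectLibrary(rbind(entries, decoys))

    featRows <- vector("list", length(planted))
    scoreRows <- list()
    plantedMap <- character(0)
    for (j in seq_along(planted)) {
        i <- planted[j]
        fid <- sprintf("F%04d", j)
        plantedMap[fid] <- entries$suspect_id[i]
        adduct <- sample(c("radical_cation", "protonated"), 1L)
        theo <- adductMz(entries$formula[i], adduct)
        mz <- theo * (1 + stats::rnorm(1, 0, config@massNoiseSdPpm) * 1e-6)
        rt <- entries$rt_minutes[i] +
            stats::rnorm(1, config@rtNoiseMean, config@rtNoiseSd)
        ccs <- entries$ccs_a2[i] *
            (1 + stats::rnorm(1, 0, config@ccsNoiseSd) / 100)
        env <- isotopePattern(entries$formula[i], adduct)
        if (nrow(env) > 1L) {
            base <- which.max(env$relint)
            jitter <- 1 + stats::rnorm(nrow(env), 0,
                                       config@isotopeNoiseSd) / 100
            jitter[base] <- 1
            env$relint <- pmax(env$relint * jitter, 1e-3)
            # measured envelopes carry the same ppm-scale mass noise
            env$mz <- env$mz *
                (1 + stats::rnorm(nrow(env), 0, config@massNoiseSdPpm) * 1e-6)
            env$mz[base] <- mz
        } else {
            env$mz <- mz
        }
        ms2Missing <- stats::runif(1) < config@ms2MissingRate
        frg <- if (ms2Missing) .emptyFragments() else {
            k <- sample(3:6, 1L)
            data.frame(mz = sort(stats::runif(k, 50, max(60, mz - 20))),
                       intensity = stats::runif(k, 1e3, 1e6))
        }
        if (!ms2Missing) {
            scoreRows[[length(scoreRows) + 1L]] <- data.frame(
                feature_id = fid, suspect_id = entries$suspect_id[i],
                score = .truncScore(1, config@ms2TrueScore),
                stringsAsFactors = FALSE)
            dec <- decoyMap[entries$suspect_id[i]]
            if (!is.na(dec))
                scoreRows[[length(scoreRows) + 1L]] <- data.frame(
                    feature_id = fid, suspect_id = unname(dec),
                    score = .truncScore(1, config@ms2FalseScore),
                    stringsAsFactors = FALSE)
        }
        row <- data.frame(feature_id = fid, mz = mz, rt_minutes = rt,
                          ccs_a2 = ccs,
                          intensity = stats::rlnorm(1, 12, 1),
                          stringsAsFactors = FALSE)
        row$isotope_envelope <- I(list(env))
        row$ms2_fragments <- I(list(frg))
        featRows[[j]] <- row
    }
    featTab <- if (length(featRows)) do.call(rbind, featRows) else
        data.frame(feature_id = character(0), mz = numeric(0),
                   rt_minutes = numeric(0), ccs_a2 = numeric(0),
                   intensity = numeric(0))
    ms2 <- if (length(scoreRows)) do.call(rbind, scoreRows) else
        data.frame(feature_id = character(0), suspect_id = character(0),
                   score = numeric(0))
    list(library = lib, features = featureSet(featTab), ms2Scores = ms2,
         truth = groundTruth(planted = plantedMap,
                             decoyIsomers = decoyMap))
}

#' Evaluate a screening result against the planted ground truth
#'
#' The true positive rate is the fraction of retained best-per-suspect
#' candidates whose suspect matches the identity planted for that
#' feature. False positives are classified as isomer-level when the
#' matched suspect shares the molecular formula of the planted compound
#' (e.g. the isomeric decoys), else as other.
#'
#' @param result A [ScreeningResult-class] from [screenFeatures()].
#' @param truth The matching [GroundTruth-class].
#' @param library The [SuspectLibrary-class] screened against (used to
#'   look up formulas for the isomer classification).
#' @return List with `tpRate` (fraction, `NA` when nothing was
#'   retained), `fpIsomer`, `fpOther`, `nRetained` and `stageCounts`.
#' @export
evaluateScreening <- function(result, truth, library) {
    cand <- candidates(result)
    ret <- cand[cand$retained, , drop = FALSE]
    unknown <- setdiff(ret$feature_id, names(truth@planted))
    if (length(unknown))
        .inputError(sprintf(
            "retained feature id(s) absent from ground truth: %s",
            paste(unknown, collapse = ", ")))
    lib <- suspectEntries(library)
    formulaOf <- stats::setNames(lib$formula, lib$suspect_id)
    nRet <- nrow(ret)
    if (nRet == 0L)
        return(list(tpRate = NA_real_, fpIsomer = 0L, fpOther = 0L,
                    nRetained = 0L, stageCounts = stageCounts(result)))
    trueId <- unname(truth@planted[ret$feature_id])
    correct <- ret$suspect_id == trueId
    fp <- !correct
    isomer <- fp & formulaOf[ret$suspect_id] == formulaOf[trueId]
    list(tpRate = sum(correct) / nRet,
         fpIsomer = sum(isomer, na.rm = TRUE),
         fpOther = sum(fp & !isomer, na.rm = TRUE),
         nRetained = nRet,
         stageCounts = stageCounts(result))
}

# ------------------------------------------------------------- truth I/O

#' Write / read ground truth as delimited text
#'
#' A single long-format CSV with columns `record_type` (`planted` or
#' `decoy`), `key` (feature id / true suspect id) and `value` (true
#' suspect id / decoy suspect id).
#'
#' @param truth A [GroundTruth-class].
#' @param path File path.
#' @return `writeGroundTruth()` returns `path` invisibly;
#'   `readGroundTruth()` returns a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
    part <- function(type, x) {
        if (!length(x))
            return(data.frame(record_type = character(0),
                              key = character(0), value = character(0)))
        data.frame(record_type = type, key = names(x), value = unname(x))
    }
    out <- rbind(part("planted", truth@planted),
                 part("decoy", truth@decoyIsomers))
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    raw <- .readDelimited(path)
    missing <- setdiff(c("record_type", "key", "value"), names(raw))
    if (length(missing))
        .inputError(sprintf("ground truth %s: missing column(s) %s", path,
                            paste(missing, collapse = ", ")))
    pl <- raw[raw$record_type == "planted", ]
    de <- raw[raw$record_type == "decoy", ]
    groundTruth(planted = stats::setNames(as.character(pl$value),
                                          pl$key),
                decoyIsomers = stats::setNames(as.character(de$value),
                                               de$key))
}
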