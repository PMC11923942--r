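# Measured-feature tables, NIST MSP spectra, fragmentation-scorer input
# files and MS2 similarity score tables.

# "mz:value;mz:value" pair-list codec used for envelopes and fragments
.encodePairs <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return("")
    paste(sprintf("%.12g:%.12g", df[[1L]], df[[2L]]), collapse = ";")
}

.decodePairs <- function(text, names) {
    out <- stats::setNames(data.frame(numeric(0), numeric(0)), names)
    if (is.na(text) || !nzchar(trimws(text))) return(out)
    parts <- strsplit(trimws(text), ";", fixed = TRUE)[[1L]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    if (any(lengths(kv) != 2L))
        .inputError(sprintf("malformed pair list '%s'", text))
    m <- suppressWarnings(vapply(kv, function(p) as.numeric(p), numeric(2)))
    if (any(is.na(m)))
        .inputError(sprintf("non-numeric value in pair list '%s'", text))
    stats::setNames(data.frame(m[1L, ], m[2L, ]), names)
}

#' Read a measured feature table from delimited text
#'
#' Expects a header and columns `feature_id`, `mz`, `rt_minutes`,
#' `ccs_a2`, `intensity`, `isotope_envelope`, `ms2_fragments`. The
#' envelope and fragment columns hold semicolon-joined `mz:value` pairs
#' (relative intensity in percent of the base peak for the envelope,
#' arbitrary intensity for fragments); empty cells mean no envelope /
#' no fragments. Rows violating the invariants (non-positive values,
#' non-numeric cells, envelope without a 100 percent base peak) are
#' skipped with a warning naming the row number. Valid rows are kept in
#' file order.
#'
#' @param path Path to the delimited file (comma or tab separated).
#' @return A [FeatureSet-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path) {
    raw <- .readDelimited(path)
    required <- c("feature_id", "mz", "rt_minutes", "ccs_a2", "intensity")
    missing <- setdiff(required, names(raw))
    if (length(missing))
        .inputError(sprintf("feature table %s: missing column(s) %s", path,
                            paste(missing, collapse = ", ")))
    for (nm in c("isotope_envelope", "ms2_fragments"))
        if (!nm %in% names(raw)) raw[[nm]] <- ""
    n <- nrow(raw)
    skipped <- character(0)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
        row <- raw[i, ]
        vals <- suppressWarnings(as.numeric(c(row$mz, row$rt_minutes,
                                              row$ccs_a2, row$intensity)))
        if (any(is.na(vals))) {
            skipped <- c(skipped, sprintf("row %d: non-numeric cell", i))
            next
        }
        if (any(vals <= 0)) {
            skipped <- c(skipped,
                         sprintf("row %d: non-positive mz/rt/ccs/intensity", i))
            next
        }
        env <- tryCatch(.decodePairs(row$isotope_envelope,
                                     c("mz", "relint")),
                        error = function(e) e)
        frg <- tryCatch(.decodePairs(row$ms2_fragments,
                                     c("mz", "intensity")),
                        error = function(e) e)
        if (inherits(env, "error") || inherits(frg, "error")) {
            skipped <- c(skipped, sprintf("row %d: malformed pair list", i))
            next
        }
        if (nrow(env) && !any(abs(env$relint - 100) < 1e-9)) {
            skipped <- c(skipped,
                         sprintf("row %d: envelope lacks a 100%% base peak", i))
            next
        }
        rows[[i]] <- data.frame(feature_id = as.character(row$feature_id),
                                mz = vals[1L], rt_minutes = vals[2L],
                                ccs_a2 = vals[3L], intensity = vals[4L],
                                stringsAsFactors = FALSE)
        rows[[i]]$isotope_envelope <- I(list(env))
        rows[[i]]$ms2_fragments <- I(list(frg))
    }
    ok <- !vapply(rows, is.null, logical(1))
    if (length(skipped))
        warning(sprintf("readFeatureTable: skipped %d row(s):\n  %s",
                        length(skipped), paste(skipped, collapse = "\n  ")))
    tab <- if (any(ok)) do.call(rbind, rows[ok]) else
        data.frame(feature_id = character(0), mz = numeric(0),
                   rt_minutes = numeric(0), ccs_a2 = numeric(0),
                   intensity = numeric(0))
    featureSet(tab)
}

#' Write a measured feature table to delimited text
#'
#' Inverse of [readFeatureTable()]; numbers are written with 12
#' significant digits so a read-write-read cycle is loss-free at working
#' precision.
#'
#' @param featureSet A [FeatureSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(featureSet, path) {
    f <- features(featureSet)
    out <- data.frame(
        feature_id = f$feature_id,
        mz = .num2str(f$mz), rt_minutes = .num2str(f$rt_minutes),
        ccs_a2 = .num2str(f$ccs_a2), intensity = .num2str(f$intensity),
        isotope_envelope = vapply(f$isotope_envelope, .encodePairs,
                                  character(1)),
        ms2_fragments = vapply(f$ms2_fragments, .encodePairs, character(1)),
        stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

# ------------------------------------------------------------------- MSP

#' Read spectra from a NIST MSP library file
#'
#' Permissive reader for the NIST MSP text dialect: each record holds
#' `Key: value` header lines (at least `Name` and `Num Peaks`; the
#' precursor is taken from `PrecursorMZ` or, failing that, `MW`),
#' followed by exactly `Num Peaks` peak lines of space- or tab-separated
#' `mz intensity` pairs. Unknown header keys are preserved but ignored.
#' Records are separated by blank lines.
#'
#' @param path Path to the MSP file.
#' @return A list of records, each a list with `name`, `precursor_mz`
#'   (may be `NA`), `peaks` (`data.frame` with `mz`, `intensity`) and
#'   `extra` (named character vector of the remaining header fields).
#' @seealso [writeMsp()]
#' @export
readMsp <- function(path) {
    if (!file.exists(path))
        .inputError(sprintf("file not found: %s", path))
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    records <- list()
    i <- 1L
    n <- length(lines)
    while (i <= n) {
        while (i <= n && !nzchar(trimws(lines[i]))) i <- i + 1L
        if (i > n) break
        headers <- character(0)
        while (i <= n && grepl(":", lines[i], fixed = TRUE) &&
               grepl("^[A-Za-z]", lines[i])) {
            key <- trimws(sub(":.*$", "", lines[i]))
            val <- trimws(sub("^[^:]*:", "", lines[i]))
            headers[key] <- val
            i <- i + 1L
            if (tolower(key) == "num peaks") break
        }
        lk <- tolower(names(headers))
        name <- if ("name" %in% lk) headers[[which(lk == "name")[1L]]] else
            sprintf("record %d", length(records) + 1L)
        if (!"num peaks" %in% lk)
            .inputError(sprintf("MSP record '%s': missing 'Num Peaks'", name))
        npeaks <- as.integer(headers[[which(lk == "num peaks")[1L]]])
        peakLines <- character(0)
        while (i <= n && nzchar(trimws(lines[i]))) {
            peakLines <- c(peakLines, trimws(lines[i]))
            i <- i + 1L
        }
        if (length(peakLines) != npeaks)
            .inputError(sprintf(
                "MSP record '%s': Num Peaks is %d but %d peak line(s) found",
                name, npeaks, length(peakLines)))
        peaks <- if (npeaks > 0L) {
            m <- do.call(rbind, lapply(strsplit(peakLines, "[ \t]+"),
                                       function(p) as.numeric(p[1:2])))
            if (any(is.na(m)))
                .inputError(sprintf("MSP record '%s': non-numeric peak line",
                                    name))
            data.frame(mz = m[, 1L], intensity = m[, 2L])
        } else data.frame(mz = numeric(0), intensity = numeric(0))
        prec <- NA_real_
        if ("precursormz" %in% lk)
            prec <- as.numeric(headers[[which(lk == "precursormz")[1L]]])
        else if ("mw" %in% lk)
            prec <- as.numeric(headers[[which(lk == "mw")[1L]]])
        extra <- headers[!lk %in% c("name", "precursormz", "num peaks")]
        records[[length(records) + 1L]] <-
            list(name = name, precursor_mz = prec, peaks = peaks,
                 extra = extra)
    }
    records
}

#' Write spectra to a NIST MSP library file
#'
#' @param records List of records as returned by [readMsp()] (fields
#'   `name`, `precursor_mz`, `peaks`; `extra` headers are re-emitted).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMsp <- function(records, path) {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (rec in records) {
        writeLines(sprintf("Name: %s", rec$name), con)
        if (!is.null(rec$precursor_mz) && !is.na(rec$precursor_mz))
            writeLines(sprintf("PrecursorMZ: %.12g", rec$precursor_mz), con)
        for (key in names(rec$extra))
            writeLines(sprintf("%s: %s", key, rec$extra[[key]]), con)
        writeLines(sprintf("Num Peaks: %d", nrow(rec$peaks)), con)
        if (nrow(rec$peaks))
            writeLines(sprintf("%.12g %.12g", rec$peaks$mz,
                               rec$peaks$intensity), con)
        writeLines("", con)
    }
    invisible(path)
}

# ------------------------------------------- fragmentation-scorer export

.IONIZATION_LABEL <- c(radical_cation = "[M]+", protonated = "[M+H]+",
                       deprotonated = "[M-H]-")

#' Export one candidate as fragmentation-scorer input
#'
#' Writes the block-structured plain-text record consumed by external
#' formula/structure scorers: the compound name, declared formula and
#' adduct, the parent ion m/z, the InChIKey and the MS2 peak list. The
#' candidate's identity is declared because by this point in the workflow
#' the candidate is already constrained by MS1, RT and CCS.
#'
#' @param feature One-row slice of [features()] (or a list with the same
#'   fields) carrying at least one MS2 fragment.
#' @param suspect One-row slice of [suspectEntries()] for the declared
#'   candidate.
#' @param adduct Declared adduct kind, see [adductKinds()].
#' @param path Output path (conventionally `<feature>_<suspect>.ms`).
#' @return Invisibly, `path`.
#' @export
exportFragmentationInput <- function(feature, suspect, adduct, path) {
    adduct <- match.arg(adduct, adductKinds())
    frg <- feature$ms2_fragments
    if (is.list(frg) && !is.data.frame(frg)) frg <- frg[[1L]]
    if (is.null(frg) || nrow(frg) == 0L)
        .inputError(sprintf(
            "feature %s has no MS2 fragments; nothing to export",
            feature$feature_id))
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(
        sprintf(">compound %s", suspect$suspect_id),
        sprintf(">formula %s", suspect$formula),
        sprintf(">ionization %s", .IONIZATION_LABEL[[adduct]]),
        sprintf(">parentmass %.12g", feature$mz),
        sprintf("#inchikey %s",
                ifelse(is.na(suspect$inchikey), "", suspect$inchikey)),
        "",
        ">ms2",
        sprintf("%.12g %.12g", frg$mz, frg$intensity)), con)
    invisible(path)
}

# ------------------------------------------------------------ MS2 scores

#' Read MS2 similarity scores from delimited text
#'
#' Columns `feature_id`, `suspect_id`, `score` with scores as fractions
#' in `[0, 1]`. Out-of-range or non-numeric scores are rejected (the rows
#' are dropped with a warning), never clamped.
#'
#' @param path Path to the delimited file.
#' @return `data.frame` with columns `feature_id`, `suspect_id`, `score`.
#' @export
readMs2Scores <- function(path) {
    raw <- .readDelimited(path)
    missing <- setdiff(c("feature_id", "suspect_id", "score"), names(raw))
    if (length(missing))
        .inputError(sprintf("MS2 score table %s: missing column(s) %s",
                            path, paste(missing, collapse = ", ")))
    if (nrow(raw) == 0L)
        return(data.frame(feature_id = character(0),
                          suspect_id = character(0), score = numeric(0)))
    score <- suppressWarnings(as.numeric(raw$score))
    bad <- is.na(score) | score < 0 | score > 1
    if (any(bad))
        warning(sprintf(
            "readMs2Scores: rejected %d row(s) with scores outside [0, 1]: row %s",
            sum(bad), paste(which(bad), collapse = ", ")))
    data.frame(feature_id = as.character(raw$feature_id)[!bad],
               suspect_id = as.character(raw$suspect_id)[!bad],
               score = score[!bad], stringsAsFactors = FALSE)
}

#' Write MS2 similarity scores to delimited text
#'
#' @param scores `data.frame` with columns `feature_id`, `suspect_id`,
#'   `score`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMs2Scores <- function(scores, path) {
    out <- data.frame(feature_id = scores$feature_id,
                      suspect_id = scores$suspect_id,
                      score = .num2str(scores$score))
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    invisible(path)
}
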