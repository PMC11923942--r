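# Delimited-text I/O for suspect libraries and RI calibration tables.

# sniff comma vs tab on the header line
.readDelimited <- function(path) {
    if (!file.exists(path))
        .inputError(sprintf("file not found: %s", path))
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, comment.char = "",
                      quote = "\"", check.names = TRUE,
                      colClasses = NA, na.strings = c("NA", ""))
}

.num2str <- function(x) {
    out <- sprintf("%.12g", x)
    out[is.na(x)] <- ""
    out
}

#' Read a suspect library from delimited text
#'
#' Expects UTF-8 comma- (default) or tab-separated text with a header and
#' columns `suspect_id`, `formula`, `ccs_a2`, `ccs_source`, plus at least
#' one of `rt_minutes`, `ri_fiehn` or `ri_kovats` (optionally `cas`,
#' `inchikey`, `rt_source`). When `rt_minutes` is absent for a row, the
#' Fiehn RI (after Kovats-to-Fiehn mapping where needed) is converted to
#' RT with the supplied anchor calibration and the row's `rt_source` is
#' set to `literature_converted` unless stated. Theoretical m/z values for
#' the radical cation and protonated adducts are computed from the
#' formula. Rows that fail validation (unparseable formula, non-positive
#' values, missing RT information) are skipped with a warning; duplicate
#' compounds (by InChIKey when present, else by `suspect_id`) keep the
#' first occurrence.
#'
#' @param path Path to the delimited file.
#' @param riCalibration Optional [RICalibration-class] (Fiehn scale) used
#'   to convert RI columns to RT.
#' @param kovatsMap Optional `riMap` from [riLinearMap()] used to map
#'   `ri_kovats` onto the Fiehn scale before conversion.
#' @return A [SuspectLibrary-class].
#' @seealso [writeSuspectLibrary()]
#' @export
readSuspectLibrary <- function(path, riCalibration = NULL,
                               kovatsMap = NULL) {
    raw <- .readDelimited(path)
    required <- c("suspect_id", "formula", "ccs_a2", "ccs_source")
    missing <- setdiff(required, names(raw))
    if (length(missing))
        .inputError(sprintf("suspect library %s: missing mandatory column(s) %s",
                            path, paste(missing, collapse = ", ")))
    rtCols <- intersect(c("rt_minutes", "ri_kovats", "ri_fiehn"), names(raw))
    if (!length(rtCols))
        .inputError(sprintf(
            "suspect library %s: missing mandatory column rt_minutes (or ri_fiehn / ri_kovats)",
            path))
    n <- nrow(raw)
    for (nm in c("cas", "inchikey", "rt_source"))
        if (!nm %in% names(raw)) raw[[nm]] <- NA_character_
    for (nm in c("rt_minutes", "ri_kovats", "ri_fiehn"))
        if (!nm %in% names(raw)) raw[[nm]] <- NA_real_

    skipped <- character(0)
    keep <- logical(n)
    out <- vector("list", n)
    for (i in seq_len(n)) {
        row <- raw[i, ]
        counts <- tryCatch(parseFormula(row$formula), error = function(e) e)
        if (inherits(counts, "error")) {
            skipped <- c(skipped, sprintf("row %d (%s): %s", i,
                                          row$suspect_id,
                                          conditionMessage(counts)))
            next
        }
        rt <- row$rt_minutes
        src <- row$rt_source
        if (is.na(rt)) {
            fiehn <- row$ri_fiehn
            if (is.na(fiehn) && !is.na(row$ri_kovats)) {
                if (is.null(kovatsMap)) {
                    skipped <- c(skipped, sprintf(
                        "row %d (%s): ri_kovats given but no Kovats-to-Fiehn map supplied",
                        i, row$suspect_id))
                    next
                }
                fiehn <- kovatsToFiehn(row$ri_kovats, kovatsMap)
            }
            if (is.na(fiehn)) {
                skipped <- c(skipped, sprintf(
                    "row %d (%s): no RT and no usable retention index", i,
                    row$suspect_id))
                next
            }
            if (is.null(riCalibration)) {
                skipped <- c(skipped, sprintf(
                    "row %d (%s): retention index given but no RI calibration supplied",
                    i, row$suspect_id))
                next
            }
            rt <- as.numeric(riToRt(fiehn, riCalibration))
            if (is.na(src)) src <- "literature_converted"
        }
        if (is.na(src)) src <- "measured"
        if (!src %in% .RT_SOURCES || !row$ccs_source %in% .CCS_SOURCES ||
            is.na(rt) || rt <= 0 || is.na(row$ccs_a2) || row$ccs_a2 <= 0) {
            skipped <- c(skipped, sprintf(
                "row %d (%s): invalid rt/ccs value or source tag", i,
                row$suspect_id))
            next
        }
        keep[i] <- TRUE
        out[[i]] <- data.frame(
            suspect_id = as.character(row$suspect_id),
            cas = as.character(row$cas),
            inchikey = as.character(row$inchikey),
            formula = formulaToString(counts),
            rt_minutes = rt, rt_source = src,
            ccs_a2 = row$ccs_a2, ccs_source = row$ccs_source,
            stringsAsFactors = FALSE)
    }
    entries <- do.call(rbind, out[keep])
    if (is.null(entries))
        entries <- data.frame(suspect_id = character(0),
                              cas = character(0), inchikey = character(0),
                              formula = character(0),
                              rt_minutes = numeric(0),
                              rt_source = character(0),
                              ccs_a2 = numeric(0),
                              ccs_source = character(0))
    # duplicate resolution: first occurrence wins
    dupKey <- ifelse(is.na(entries$inchikey), paste0("id:", entries$suspect_id),
                     paste0("ik:", entries$inchikey))
    dup <- duplicated(dupKey)
    if (any(dup)) {
        message(sprintf("readSuspectLibrary: %d duplicate compound(s) dropped (first occurrence kept): %s",
                        sum(dup),
                        paste(entries$suspect_id[dup], collapse = ", ")))
        entries <- entries[!dup, , drop = FALSE]
    }
    if (length(skipped))
        warning(sprintf("readSuspectLibrary: skipped %d row(s):\n  %s",
                        length(skipped), paste(skipped, collapse = "\n  ")))
    suspectLibrary(entries)
}

#' Write a suspect library to delimited text
#'
#' Writes the normalized entry table (including the computed adduct m/z
#' columns) as comma-separated UTF-8 text that [readSuspectLibrary()]
#' reads back unchanged.
#'
#' @param library A [SuspectLibrary-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSuspectLibrary <- function(library, path) {
    e <- suspectEntries(library)
    out <- data.frame(suspect_id = e$suspect_id, cas = e$cas,
                      inchikey = e$inchikey, formula = e$formula,
                      mz_radical_cation = .num2str(e$mz_radical_cation),
                      mz_protonated = .num2str(e$mz_protonated),
                      rt_minutes = .num2str(e$rt_minutes),
                      rt_source = e$rt_source,
                      ccs_a2 = .num2str(e$ccs_a2),
                      ccs_source = e$ccs_source,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    invisible(path)
}

#' Read an RI calibration anchor table
#'
#' Two-column delimited text (`index`, `rt_minutes`) of reference-compound
#' retention-index / retention-time pairs.
#'
#' @param path Path to the delimited file.
#' @param indexScale `"fiehn"` (default) or `"kovats"`.
#' @return An [RICalibration-class].
#' @export
readRiCalibration <- function(path, indexScale = "fiehn") {
    raw <- .readDelimited(path)
    missing <- setdiff(c("index", "rt_minutes"), names(raw))
    if (length(missing))
        .inputError(sprintf("RI calibration %s: missing column(s) %s", path,
                            paste(missing, collapse = ", ")))
    riCalibration(raw$index, raw$rt_minutes, indexScale = indexScale)
}
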