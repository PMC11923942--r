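test_that("Kovats-to-Fiehn mapping is an exact least-squares line", {
    m <- riLinearMap(c(1000, 2000), c(1100, 2100))
    expect_equal(kovatsToFiehn(1500, m), 1600)
    ident <- riLinearMap(c(1000, 1500, 2000), c(1000, 1500, 2000))
    expect_equal(kovatsToFiehn(1500, ident), 1500)
    expect_error(riLinearMap(1000, 1100), "at least 2")
    # map followed by its inverse is identity
    m2 <- riLinearMap(c(900, 1400, 2100), c(1020, 1530, 2280))
    inv <- inverseRiMap(m2)
    ri <- seq(800, 2400, by = 50)
    expect_equal(kovatsToFiehn(kovatsToFiehn(ri, m2), inv), ri,
                 tolerance = 1e-6 / 1000)
})

test_that("RI-to-RT interpolation hits anchors, midpoints and flags extrapolation", {
    cal <- riCalibration(c(800, 1000, 1400), c(5, 10, 16))
    expect_equal(as.numeric(riToRt(1000, cal)), 10)
    expect_equal(as.numeric(riToRt(900, cal)), 7.5)
    below <- riToRt(700, cal)
    expect_equal(as.numeric(below), 2.5)
    expect_true(attr(below, "extrapolated"))
    expect_false(attr(riToRt(1200, cal), "extrapolated"))
    # monotone over a fine grid spanning the anchors
    rts <- as.numeric(riToRt(seq(800, 1400, by = 10), cal))
    expect_true(all(diff(rts) > 0))
    expect_error(riCalibration(c(800, 800), c(5, 10)),
                 "strictly increasing")
    expect_error(riToRt(900, riCalibration(c(800, 1000), c(5, 10),
                                           indexScale = "kovats")),
                 "Fiehn")
})

test_that("RT threshold calibration reproduces the published interval endpoints", {
    # residual summaries: predicted 0.086 +- 1.13 min, literature 0.15 +- 0.69
    # three symmetric residuals -s, 0, +s about mu have sample SD exactly s
    mkDeltas <- function(mu, s) mu + s * c(-1, 0, 1)
    pred <- calibrateRtThresholds(mkDeltas(0.086, 1.13))
    expect_equal(pred$high, c(-1.044, 1.216), tolerance = 1e-9)
    expect_equal(pred$low, c(-2.174, 2.346), tolerance = 1e-9)
    lit <- calibrateRtThresholds(mkDeltas(0.15, 0.69))
    expect_equal(lit$high, c(-0.54, 0.84), tolerance = 1e-9)
    expect_error(calibrateRtThresholds(c(0.1, 0.2)), "at least 3")
    expect_warning(thr <- calibrateRtThresholds(c(0.3, 0.3, 0.3)),
                   "degenerate")
    expect_equal(thr$high, c(0.3, 0.3))
})

test_that("RT threshold calibration is translation-equivariant", {
    set.seed(4)
    d <- rnorm(30, 0.1, 0.8)
    base <- calibrateRtThresholds(d)
    shifted <- calibrateRtThresholds(d + 1.7)
    expect_equal(shifted$high, base$high + 1.7, tolerance = 1e-12)
    expect_equal(shifted$low, base$low + 1.7, tolerance = 1e-12)
})

test_that("default thresholds carry the published CCS bounds and validate", {
    thr <- defaultThresholds()
    expect_equal(thr@ccsLiterature, c(2, 3))
    expect_equal(thr@ccsPredicted, c(5, 7))
    expect_true(methods::validObject(thr))
    # high interval strictly inside low for every RT source
    for (iv in thr@rtIntervals) {
        expect_lt(iv$low[1], iv$high[1])
        expect_lt(iv$high[2], iv$low[2])
    }
})

test_that("suspect library reader converts RI columns and skips bad rows", {
    cal <- riCalibration(c(800, 1000, 2000), c(5, 10, 30))
    kmap <- riLinearMap(c(1000, 2000), c(1100, 2100))
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "suspect_id,inchikey,formula,rt_minutes,ri_fiehn,ri_kovats,ccs_a2,ccs_source",
        "A,KEYA,C10H8,12.5,,,124,literature",
        "B,KEYB,C6Cl6,,1000,,152,literature",
        "C,KEYC,C12H6Br2O,,,1900,185,predicted",
        "D,KEYD,C6Qx6,9.9,,,140,literature"), path)
    expect_warning(lib <- readSuspectLibrary(path, riCalibration = cal,
                                             kovatsMap = kmap),
                   "skipped 1")
    e <- suspectEntries(lib)
    expect_equal(e$suspect_id, c("A", "B", "C"))
    expect_equal(e$rt_minutes[e$suspect_id == "A"], 12.5)
    expect_equal(e$rt_source[e$suspect_id == "A"], "measured")
    expect_equal(e$rt_minutes[e$suspect_id == "B"], 10)
    expect_equal(e$rt_source[e$suspect_id == "B"], "literature_converted")
    # kovats 1900 -> fiehn 2000 -> 30 min
    expect_equal(e$rt_minutes[e$suspect_id == "C"], 30)
    # adduct m/z computed from the formula
    expect_equal(e$mz_radical_cation[e$suspect_id == "A"],
                 adductMz("C10H8", "radical_cation"), tolerance = 1e-10)
})

test_that("suspect library reader reports missing columns and duplicates", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("suspect_id,rt_minutes", "A,10"), path)
    expect_error(readSuspectLibrary(path), "formula",
                 class = "mdscreenInputError")
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "suspect_id,inchikey,formula,rt_minutes,ccs_a2,ccs_source",
        "A,SAMEKEY,C10H8,10,124,literature",
        "B,SAMEKEY,C10H8,11,125,literature"), path2)
    expect_message(lib <- readSuspectLibrary(path2), "duplicate")
    expect_equal(suspectEntries(lib)$suspect_id, "A")
})

test_that("suspect library survives a write-read round trip", {
    lib <- toyLibrary()
    path <- withr::local_tempfile(fileext = ".csv")
    writeSuspectLibrary(lib, path)
    back <- readSuspectLibrary(path)
    e1 <- suspectEntries(lib)
    e2 <- suspectEntries(back)
    expect_equal(e2$suspect_id, e1$suspect_id)
    expect_equal(e2$formula, e1$formula)
    expect_equal(e2$rt_minutes, e1$rt_minutes, tolerance = 1e-9)
    expect_equal(e2$ccs_a2, e1$ccs_a2, tolerance = 1e-9)
    expect_equal(e2$rt_source, e1$rt_source)
    # and a second cycle is byte-stable
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeSuspectLibrary(back, path2)
    expect_identical(readLines(path), readLines(path2))
})
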