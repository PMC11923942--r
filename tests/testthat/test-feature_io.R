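test_that("feature table reader parses envelopes and rejects bad rows", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c(
        "feature_id,mz,rt_minutes,ccs_a2,intensity,isotope_envelope,ms2_fragments",
        "F1,300.0,12.1,180,1e5,300.0:100;302.0:65,",
        "F2,150.0,8.2,140,2e4,150.0:100,77.0:1000;95.0:500",
        "F3,210.0,9.0,-5,1e4,,",
        "F4,abc,9.0,150,1e4,,"), path)
    expect_warning(fs <- readFeatureTable(path), "skipped 2")
    f <- features(fs)
    expect_equal(f$feature_id, c("F1", "F2"))       # order preserved
    env <- f$isotope_envelope[[1]]
    expect_equal(env$mz, c(300, 302))
    expect_equal(env$relint, c(100, 65))
    expect_equal(nrow(f$ms2_fragments[[1]]), 0L)    # empty fragment field
    expect_equal(f$ms2_fragments[[2]]$mz, c(77, 95))
})

test_that("feature table reader names missing columns", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature_id,mz", "F1,100"), path)
    expect_error(readFeatureTable(path), "rt_minutes",
                 class = "mdscreenInputError")
})

test_that("feature tables are loss-free through write-read cycles", {
    sim <- simulateDataset(simulationConfig(nSuspects = 15, seed = 9))
    path <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(sim$features, path)
    back <- readFeatureTable(path)
    f1 <- features(sim$features)
    f2 <- features(back)
    expect_equal(f2$feature_id, f1$feature_id)
    expect_equal(f2$mz, f1$mz, tolerance = 1e-9)
    expect_equal(f2$rt_minutes, f1$rt_minutes, tolerance = 1e-9)
    for (i in seq_len(nrow(f1))) {
        expect_equal(f2$isotope_envelope[[i]]$relint,
                     f1$isotope_envelope[[i]]$relint, tolerance = 1e-9)
        expect_equal(f2$ms2_fragments[[i]]$mz, f1$ms2_fragments[[i]]$mz,
                     tolerance = 1e-9)
    }
    # second cycle is byte-stable
    path2 <- withr::local_tempfile(fileext = ".csv")
    writeFeatureTable(back, path2)
    expect_identical(readLines(path), readLines(path2))
})

test_that("MSP write-read round-trips a 20-record set", {
    set.seed(21)
    records <- lapply(1:20, function(i) {
        k <- sample(0:6, 1)
        list(name = sprintf("compound-%02d", i),
             precursor_mz = round(runif(1, 100, 500), 4),
             peaks = data.frame(mz = round(sort(runif(k, 50, 480)), 4),
                                intensity = round(runif(k, 1, 999), 1)),
             extra = c(Formula = "C10H8"))
    })
    path <- withr::local_tempfile(fileext = ".msp")
    writeMsp(records, path)
    back <- readMsp(path)
    expect_length(back, 20L)
    for (i in seq_along(records)) {
        expect_equal(back[[i]]$name, records[[i]]$name)
        expect_equal(back[[i]]$precursor_mz, records[[i]]$precursor_mz)
        expect_equal(back[[i]]$peaks$mz, records[[i]]$peaks$mz)
        expect_equal(back[[i]]$peaks$intensity,
                     records[[i]]$peaks$intensity)
    }
})

test_that("MSP reader enforces the Num Peaks contract", {
    path <- withr::local_tempfile(fileext = ".msp")
    writeLines(c("Name: broken", "PrecursorMZ: 128.062",
                 "Num Peaks: 3", "51.0 100", "77.0 50", ""), path)
    expect_error(readMsp(path), "broken", class = "mdscreenInputError")
    empty <- withr::local_tempfile(fileext = ".msp")
    writeLines(character(0), empty)
    expect_equal(readMsp(empty), list())
})

test_that("fragmentation-scorer export writes the declared-candidate block", {
    lib <- toyLibrary()
    feat <- exactFeature(lib, "NAP", adduct = "radical_cation",
                         nFragments = 3L)
    path <- withr::local_tempfile(fileext = ".ms")
    exportFragmentationInput(feat, suspectEntries(lib)[1, ],
                             "radical_cation", path)
    lines <- readLines(path)
    expect_equal(lines[1], ">compound NAP")
    expect_equal(lines[2], ">formula C10H8")
    expect_equal(lines[3], ">ionization [M]+")
    expect_equal(lines[4], sprintf(">parentmass %.12g", feat$mz))
    ms2At <- which(lines == ">ms2")
    expect_length(ms2At, 1L)
    expect_length(lines[(ms2At + 1):length(lines)], 3L)  # 3 peak lines
    # empty fragment list is refused
    bare <- exactFeature(lib, "NAP", nFragments = 0L)
    expect_error(exportFragmentationInput(bare, suspectEntries(lib)[1, ],
                                          "radical_cation", path),
                 "no MS2 fragments", class = "mdscreenInputError")
})

test_that("MS2 score import rejects out-of-range scores instead of clamping", {
    path <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("feature_id,suspect_id,score",
                 "f1,s1,0.724", "f1,s2,1.2", "f2,s1,-0.1"), path)
    expect_warning(sc <- readMs2Scores(path), "rejected 2")
    expect_equal(nrow(sc), 1L)
    expect_equal(sc$score, 0.724)
    empty <- withr::local_tempfile(fileext = ".csv")
    writeLines("feature_id,suspect_id,score", empty)
    expect_equal(nrow(readMs2Scores(empty)), 0L)
})
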