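test_that("the simulator is deterministic under its seed", {
    a <- simulateDataset(simulationConfig(nSuspects = 30, seed = 7,
                                          isomerDecoyRate = 0.3))
    b <- simulateDataset(simulationConfig(nSuspects = 30, seed = 7,
                                          isomerDecoyRate = 0.3))
    expect_identical(suspectEntries(a$library), suspectEntries(b$library))
    expect_identical(features(a$features), features(b$features))
    expect_identical(a$ms2Scores, b$ms2Scores)
    expect_identical(a$truth@planted, b$truth@planted)
    c <- simulateDataset(simulationConfig(nSuspects = 30, seed = 8))
    expect_false(identical(suspectEntries(a$library),
                           suspectEntries(c$library)))
})

test_that("a noiseless, decoy-free dataset is recovered completely", {
    cfg <- simulationConfig(nSuspects = 40, fractionPresent = 1,
                            isomerDecoyRate = 0, rtNoiseSd = 0,
                            ccsNoiseSd = 0, massNoiseSdPpm = 0,
                            isotopeNoiseSd = 0, ms2MissingRate = 0.3,
                            seed = 5)
    sim <- simulateDataset(cfg)
    expect_equal(length(sim$features), 40L)
    res <- screenFeatures(sim$features, sim$library, sim$ms2Scores)
    ev <- evaluateScreening(res, sim$truth, sim$library)
    expect_equal(ev$tpRate, 1)
    expect_equal(ev$nRetained, 40L)
    expect_equal(ev$fpIsomer + ev$fpOther, 0L)
    expect_equal(unname(stageCounts(res)), rep(40L, 4))
})

test_that("simulation edge cases behave as contracted", {
    empty <- simulateDataset(simulationConfig(nSuspects = 10,
                                              fractionPresent = 0,
                                              seed = 2))
    expect_equal(length(empty$features), 0L)
    expect_equal(length(empty$truth@planted), 0L)
    # library formulas are unique (decoys aside) and halogen-rich
    sim <- simulateDataset(simulationConfig(nSuspects = 60, seed = 3))
    e <- suspectEntries(sim$library)
    expect_false(anyDuplicated(e$formula) > 0)
    expect_true(all(grepl("Cl|Br", e$formula)))
})

test_that("isomeric decoys share the formula but shift RT and CCS", {
    sim <- simulateDataset(simulationConfig(nSuspects = 40, seed = 13,
                                            isomerDecoyRate = 0.5))
    e <- suspectEntries(sim$library)
    expect_gt(length(sim$truth@decoyIsomers), 0L)
    for (tru in names(sim$truth@decoyIsomers)) {
        dec <- sim$truth@decoyIsomers[[tru]]
        expect_equal(e$formula[e$suspect_id == dec],
                     e$formula[e$suspect_id == tru])
        relCcs <- abs(e$ccs_a2[e$suspect_id == dec] /
                          e$ccs_a2[e$suspect_id == tru] - 1) * 100
        expect_gte(relCcs, 3 - 1e-9)
        expect_lte(relCcs, 5 + 1e-9)
    }
})

test_that("evaluation rejects unknown features and handles empty retention", {
    sim <- simulateDataset(simulationConfig(nSuspects = 20, seed = 4))
    res <- screenFeatures(sim$features, sim$library, sim$ms2Scores)
    disjoint <- groundTruth(planted = c(ZZZ1 = "S0001"))
    expect_error(evaluateScreening(res, disjoint, sim$library),
                 "absent from ground truth", class = "mdscreenInputError")
    # empty retained set: tp rate is not applicable
    emptyRes <- suppressWarnings(screenFeatures(
        featureSet(data.frame(feature_id = "FX", mz = 1234.5,
                              rt_minutes = 10, ccs_a2 = 150,
                              intensity = 1)), sim$library))
    ev <- evaluateScreening(emptyRes, sim$truth, sim$library)
    expect_true(is.na(ev$tpRate))
    expect_equal(ev$nRetained, 0L)
})

test_that("true positive rate does not improve when CCS noise grows", {
    tpAt <- function(ccsSd) {
        mean(vapply(1:6, function(s) {
            cfg <- simulationConfig(nSuspects = 60, seed = s,
                                    isomerDecoyRate = 0.4,
                                    ccsNoiseSd = ccsSd)
            sim <- simulateDataset(cfg)
            res <- suppressWarnings(
                screenFeatures(sim$features, sim$library, sim$ms2Scores))
            ev <- evaluateScreening(res, sim$truth, sim$library)
            if (is.na(ev$tpRate)) 1 else ev$tpRate
        }, numeric(1)))
    }
    expect_gte(tpAt(0.5), tpAt(3.5))
})

test_that("ground truth round-trips through its delimited file", {
    truth <- groundTruth(planted = c(F1 = "S1", F2 = "S2"),
                         decoyIsomers = c(S1 = "S1_iso"))
    path <- withr::local_tempfile(fileext = ".csv")
    writeGroundTruth(truth, path)
    back <- readGroundTruth(path)
    expect_identical(back@planted, truth@planted)
    expect_identical(back@decoyIsomers, truth@decoyIsomers)
})
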