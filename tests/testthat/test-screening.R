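cfgDefault <- scoringConfig()

test_that("mass gate applies the split ppm/mDa rule with strict bounds", {
    g <- massGate(c(300.0012, 300.0018), 300.0, cfgDefault)
    expect_equal(g$ppm, c(4, 6), tolerance = 1e-6)
    expect_equal(g$pass, c(TRUE, FALSE))
    g2 <- massGate(c(150.0019, 150.0021), 150.0, cfgDefault)
    expect_equal(g2$mda, c(1.9, 2.1), tolerance = 1e-6)
    expect_equal(g2$pass, c(TRUE, FALSE))
    # at exactly the boundary the ppm rule applies: 1.5 mDa = 7.5 ppm fails
    expect_false(massGate(200.0015, 200.0, cfgDefault)$pass)
    expect_error(massGate(-1, 100), "positive")
})

test_that("isotope gate matches ions, computes gm deviation and bypasses monoisotopics", {
    theory <- isotopePattern("C6Cl6", "radical_cation")
    # identical envelope: zero deviation, pass
    g <- isotopeGate(theory, theory, cfgDefault)
    expect_true(g$pass)
    expect_equal(g$gmDeviation, 0)
    expect_false(g$bypass)
    # single matched isotope at exactly 5% deviation fails the strict gate
    theory2 <- data.frame(mz = c(283.81, 285.81), relint = c(100, 64))
    env2 <- data.frame(mz = c(283.81, 285.81), relint = c(100, 60.8))
    g2 <- isotopeGate(env2, theory2, cfgDefault)
    expect_equal(g2$gmDeviation, 5, tolerance = 1e-9)
    expect_false(g2$pass)
    # 4.9% passes
    env3 <- data.frame(mz = c(283.81, 285.81), relint = c(100, 64 * 0.951))
    expect_true(isotopeGate(env3, theory2, cfgDefault)$pass)
    # no non-base isotope detected: fail
    g4 <- isotopeGate(data.frame(mz = 283.81, relint = 100), theory2,
                      cfgDefault)
    expect_false(g4$pass)
    expect_equal(g4$nMatched, 0L)
    # monoisotopic compound: vacuous pass with bypass flag
    g5 <- isotopeGate(data.frame(mz = 127, relint = 100),
                      isotopePattern("I"), cfgDefault)
    expect_true(g5$pass)
    expect_true(g5$bypass)
})

test_that("delta operators are signed with the measured-minus-reference convention", {
    expect_equal(deltaRt(10, 10), 0)
    expect_equal(deltaRt(10.5, 10), 0.5)
    expect_equal(deltaRt(9, 10), -1)
    expect_equal(deltaCcs(200, 200), 0)
    expect_equal(deltaCcs(204, 200), 2)
    expect_equal(deltaCcs(186, 200), -7)
})

test_that("continuous score is 1 inside high, 0 outside low, linear between", {
    expect_equal(continuousScore(c(0, 1.5, -1.99), 2, 3), c(1, 1, 1))
    expect_equal(continuousScore(2.5, 2, 3), 0.5)
    expect_equal(continuousScore(-2.5, 2, 3), 0.5)
    expect_equal(continuousScore(c(3.5, -3.01, 3), 2, 3), c(0, 0, 0))
    # asymmetric RT intervals decay toward the low boundary on the same side
    high <- c(-0.54, 0.84); low <- c(-1.23, 1.53)
    expect_equal(continuousScore(0.84 + 0.345, high, low), 0.5)
    expect_equal(continuousScore(-0.54 - 0.345, high, low), 0.5)
    expect_equal(continuousScore(0.15, high, low), 1)
    expect_error(continuousScore(1, 3, 3), "strictly inside")
})

test_that("continuous score is continuous at thresholds and monotone beyond high", {
    eps <- 1e-9
    expect_equal(continuousScore(2 + eps, 2, 3), 1, tolerance = 1e-6)
    expect_equal(continuousScore(3 - eps, 2, 3), 0, tolerance = 1e-6)
    d <- seq(2, 3.6, by = 0.01)
    s <- continuousScore(d, 2, 3)
    expect_true(all(diff(s) <= 1e-12))
    s2 <- continuousScore(-d, 2, 3)
    expect_true(all(diff(s2) <= 1e-12))
    # pluggable score shape: quadratic decay still hits the endpoints
    sq <- continuousScore(c(1, 2.5, 3.2), 2, 3, shape = function(u) u^2)
    expect_equal(sq, c(1, 0.75, 0))
})

test_that("score fusion uses fixed weights with absent MS2 contributing zero", {
    expect_equal(fuseScores(1, 1, 1, cfgDefault), 1)
    expect_equal(fuseScores(1, 1, NA, cfgDefault), 0.6, tolerance = 1e-12)
    expect_equal(fuseScores(0, 0, 0, cfgDefault), 0)
    expect_equal(fuseScores(0.5, 1, 0.8, cfgDefault),
                 0.2 * 0.5 + 0.4 * 1 + 0.4 * 0.8)
    # monotone in each argument
    base <- fuseScores(0.5, 0.5, 0.5, cfgDefault)
    expect_gt(fuseScores(0.6, 0.5, 0.5, cfgDefault), base)
    expect_gt(fuseScores(0.5, 0.6, 0.5, cfgDefault), base)
    expect_gt(fuseScores(0.5, 0.5, 0.6, cfgDefault), base)
    expect_error(fuseScores(1.2, 0, 0, cfgDefault), "0, 1")
})

test_that("screening a perfectly matching feature yields a full-score retained hit", {
    lib <- toyLibrary()
    feat <- toyFeatureSet(exactFeature(lib, "HCB", "radical_cation"))
    ms2 <- data.frame(feature_id = "F1", suspect_id = "HCB", score = 1)
    res <- screenFeatures(feat, lib, ms2)
    cand <- candidates(res)
    expect_equal(nrow(cand), 1L)
    expect_equal(cand$multidimensional_score, 1, tolerance = 1e-9)
    expect_true(cand$retained)
    expect_equal(unname(stageCounts(res)), c(1L, 1L, 1L, 1L))
})

test_that("a CCS deviation beyond the low threshold stops the candidate at stage one", {
    lib <- toyLibrary()
    feat <- toyFeatureSet(exactFeature(lib, "HCB", ccsFactor = 1.10))
    res <- screenFeatures(feat, lib)
    expect_equal(unname(stageCounts(res)), c(1L, 0L, 0L, 0L))
})

test_that("only the highest-scoring candidate per suspect is retained", {
    lib <- toyLibrary()
    good <- exactFeature(lib, "HCB", featureId = "F1")
    worse <- exactFeature(lib, "HCB", featureId = "F2", rtOffset = 1.2)
    feat <- toyFeatureSet(good, worse)
    ms2 <- data.frame(feature_id = c("F1", "F2"),
                      suspect_id = "HCB", score = c(0.9, 0.9))
    res <- screenFeatures(feat, lib, ms2)
    cand <- candidates(res)
    expect_equal(nrow(cand), 2L)
    expect_equal(sum(cand$retained), 1L)
    expect_equal(cand$feature_id[cand$retained], "F1")
    expect_equal(stageCounts(res)[["best_retained"]], 1L)
})

test_that("without MS2, retention requires perfect RT and CCS scores", {
    lib <- toyLibrary()
    perfect <- exactFeature(lib, "HCB", featureId = "F1", nFragments = 0L)
    slightly <- exactFeature(lib, "NAP", featureId = "F2",
                             rtOffset = 1.0, nFragments = 0L)
    res <- screenFeatures(toyFeatureSet(perfect, slightly), lib)
    cand <- candidates(res)
    expect_true(cand$retained[cand$feature_id == "F1"])
    f2 <- cand[cand$feature_id == "F2", ]
    expect_lt(f2$score_rt, 1)
    expect_false(f2$retained)
})

test_that("an MS2 score only counts with enough monoisotopic fragments", {
    lib <- toyLibrary()
    oneFrag <- exactFeature(lib, "HCB", featureId = "F1", nFragments = 1L)
    ms2 <- data.frame(feature_id = "F1", suspect_id = "HCB", score = 0.9)
    res <- screenFeatures(toyFeatureSet(oneFrag), lib, ms2)
    expect_true(is.na(candidates(res)$score_ms2))
    # fused score falls back to the RT+CCS ceiling
    expect_equal(candidates(res)$multidimensional_score, 0.6,
                 tolerance = 1e-9)
})

test_that("empty inputs give an empty result with a warning", {
    lib <- toyLibrary()
    expect_warning(res <- screenFeatures(featureSet(
        data.frame(feature_id = character(0), mz = numeric(0),
                   rt_minutes = numeric(0), ccs_a2 = numeric(0),
                   intensity = numeric(0))), lib), "empty")
    expect_equal(unname(stageCounts(res)), rep(0L, 4))
    expect_equal(nrow(candidates(res)), 0L)
})

test_that("candidate ranking is deterministic with the documented tie-breaks", {
    cand <- data.frame(
        feature_id = c("F1", "F2", "F3", "F4"),
        suspect_id = c("B", "A", "C", "D"),
        adduct = "radical_cation",
        delta_ccs = c(2, 1, 1, 1),
        mass_error_ppm = c(1, 1, 2, 1),
        multidimensional_score = c(0.8, 0.8, 0.8, 0.6),
        retained = TRUE, stringsAsFactors = FALSE)
    ranked <- rankCandidates(cand)
    # score first, then |dCCS|, then |ppm|, then suspect id
    expect_equal(ranked$suspect_id, c("A", "C", "B", "D"))
    expect_equal(ranked$rank, 1:4)
})

test_that("scoring configuration round-trips through its YAML file", {
    cfg <- scoringConfig(weights = c(rt = 0.3, ccs = 0.3, ms2 = 0.4),
                         cutoff = 0.5, massTolPpm = 4)
    path <- withr::local_tempfile(fileext = ".yaml")
    writeScoringConfig(cfg, path)
    back <- readScoringConfig(path)
    expect_equal(back@weights, cfg@weights)
    expect_equal(back@cutoff, cfg@cutoff)
    expect_equal(back@massTolPpm, cfg@massTolPpm)
    expect_equal(back@thresholds@ccsLiterature,
                 cfg@thresholds@ccsLiterature)
    expect_equal(back@thresholds@rtIntervals, cfg@thresholds@rtIntervals)
})

test_that("scoring config invariants are enforced", {
    expect_error(scoringConfig(weights = c(rt = 0.5, ccs = 0.5, ms2 = 0.5)),
                 "sum to 1")
    expect_error(scoringConfig(cutoff = 0), "cutoff")
})
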