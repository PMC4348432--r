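test_that("the fixture ships 75 records with the documented composition", {
    records <- cachedFixture()
    expect_length(records, 75L)
    prof <- cachedProfileTable()
    expect_equal(sum(prof$n_stereocenters >= 1L), 24L)
    expect_equal(sum(prof$n_stereocenters == 0L), 51L)
    expect_equal(range(prof$n_C), c(1L, 13L))
    expect_equal(mean(prof$n_C), 4.9, tolerance = 0.15 / 4.9)
    expect_equal(mean(prof$nominal_mass), 126.7, tolerance = 2 / 126.7)
    expect_equal(range(prof$n_stereocenters), c(0L, 5L))
    # heavy atoms are C+N+O+S throughout this set
    expect_equal(prof$n_heavy, prof$n_C + prof$n_N + prof$n_O + prof$n_S)
})

test_that("the fixture checksum guards against silent modification", {
    shipped <- system.file("extdata", "metabolites.tsv", package = "nmrbits")
    expect_identical(unname(tools::md5sum(shipped)),
                     nmrbits:::.fixtureChecksum)
    records <- cachedFixture()   # the genuine file loads
    expect_length(records, 75L)
    # a tampered copy no longer matches the recorded checksum
    tampered <- tempfile(fileext = ".tsv")
    lines <- readLines(shipped)
    i <- grep("^formic_acid", lines)
    lines[i] <- sub("OC=O", "OCC=O", lines[i], fixed = TRUE)
    writeLines(lines, tampered)
    expect_false(identical(unname(tools::md5sum(tampered)),
                           nmrbits:::.fixtureChecksum))
})

test_that("cohort aggregation reports order statistics per level", {
    theo <- cachedTheoreticals()
    bits <- lapply(theo, levelBits)
    agg <- aggregateBits(bits)
    expect_equal(agg$min[1], 2)
    expect_equal(agg$max[1], 42)
    expect_equal(agg$min[3], 3)
    # permutation invariance
    set.seed(3)
    agg2 <- aggregateBits(sample(bits))
    expect_equal(agg$total, agg2$total)
    expect_equal(agg$median, agg2$median)
    # single metabolite: degenerate summary
    one <- aggregateBits(bits["taurine"])
    expect_equal(one$min, one$max)
    expect_equal(one$mean, one$median)
    expect_error(aggregateBits(list()), "empty")
})

test_that("group comparisons follow the two-tailed unpaired conventions", {
    same <- compareGroups(c(3, 3, 3), c(3, 3))
    expect_equal(same$p, 1)
    # closed-form check: equal n, equal variance
    a <- c(1, 2, 3, 4)
    b <- a + 10
    cg <- compareGroups(a, b)
    sp <- sqrt((var(a) + var(b)) / 2)
    tOracle <- (mean(a) - mean(b)) / (sp * sqrt(2 / 4))
    expect_equal(cg$tPooled, tOracle)
    expect_lt(cg$p, 0.001)
    # chirality contrast on the fixture: significant under both variants
    prof <- cachedProfileTable()
    chiral <- prof$n_stereocenters >= 1
    cmp <- compareGroups(prof$mice_hsqc[chiral], prof$mice_hsqc[!chiral])
    expect_lt(cmp$p, 0.05)
    expect_lt(cmp$pPooled, 0.05)
})

test_that("the simulator is seeded, bounded and reproducible", {
    fix <- cachedFixture()
    theo <- cachedTheoreticals()
    m1 <- retentionModel(seed = 5L)
    a <- simulateObservations(fix[["d_glucose"]], theo[["d_glucose"]], m1)
    b <- simulateObservations(fix[["d_glucose"]], theo[["d_glucose"]], m1)
    expect_identical(a, b)
    c2 <- simulateObservations(fix[["d_glucose"]], theo[["d_glucose"]],
                               retentionModel(seed = 6L))
    expect_false(identical(a, c2))
    # observed never exceeds theoretical, feature by feature
    for (id in c("d_glucose", "citric_acid", "hippuric_acid", "taurine")) {
        sim <- simulateObservations(fix[[id]], theo[[id]],
                                    retentionModel(seed = 9L))
        expect_length(validateVsTheory(tallyObserved(sim), theo[[id]]), 0L)
    }
    # zero retention gives the all-zero observation
    none <- tallyObserved(simulateObservations(
        fix[["taurine"]], theo[["taurine"]],
        retentionModel(0, 0, 0, 0, 0, seed = 1L)))
    expect_equal(sum(bitsVector(levelBits(none))), 0L)
})

test_that("simulated cohort totals sit near the study's observed totals", {
    fix <- cachedFixture()
    theo <- cachedTheoreticals()
    ref <- c(467, 560, 689, 771)
    ok <- vapply(1:20, function(s) {
        model <- retentionModel(seed = s)
        tot <- rowSums(vapply(names(fix), function(id) {
            sim <- simulateObservations(fix[[id]], theo[[id]], model)
            bitsVector(levelBits(tallyObserved(sim)))
        }, numeric(4)))
        all(abs(tot - ref) / ref <= 0.10)
    }, logical(1))
    expect_true(all(ok))
})

test_that("shift-family retention converges to its probability", {
    # law of large numbers on the richest metabolite
    fix <- cachedFixture()
    theo <- cachedTheoreticals()
    fracs <- vapply(1:40, function(s) {
        sim <- simulateObservations(fix[["d_glucose"]], theo[["d_glucose"]],
                                    retentionModel(seed = 1000L + s))
        nrow(sim@shifts) / theo[["d_glucose"]]@nShifts
    }, numeric(1))
    expect_equal(mean(fracs), 0.68, tolerance = 0.10)
})

test_that("cohort observations mix curated and reconstructed sets", {
    obs <- cachedObservations()
    expect_length(obs, 75L)
    expect_equal(obs[["l_fucose"]]@provenance, "curated")
    expect_equal(obs[["taurine"]]@provenance, "reconstructed_from_theory")
})

test_that("the soft-check diff report tabulates totals against references", {
    rep <- cohortDiffReport(cachedFixture())
    expect_equal(nrow(rep$perMetabolite), 75L)
    expect_equal(nrow(rep$aggregate), 4L)
    expect_true(all(c("total", "total_ref", "mean", "mean_ref") %in%
                    names(rep$aggregate)))
    # report, not assertion: totals should at least be the same magnitude
    expect_true(all(abs(rep$aggregate$total - rep$aggregate$total_ref) /
                    rep$aggregate$total_ref < 0.25))
})
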