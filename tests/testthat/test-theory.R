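test_that("shift and multiplicity counts follow the one-per-resonance rule", {
    expect_equal(unname(countShiftsAndMultiplicities(
        topoOf("CC(C)(O)C(O)=O"))), c(1L, 1L))
    expect_equal(unname(countShiftsAndMultiplicities(topoOf("CN(C)C"))),
                 c(1L, 1L))
    # no non-exchanging protons at all: zeros plus a warning note
    oxalic <- countShiftsAndMultiplicities(topoOf("OC(=O)C(O)=O"))
    expect_equal(as.integer(oxalic), c(0L, 0L))
    expect_equal(attr(oxalic, "note"), "NMR-invisible")
})

test_that("coupling counting keeps 2/3-bond paths between distinct classes", {
    expect_equal(countCouplings(topoOf("OC(=O)CCC(O)=O")), 0L)
    expect_equal(countCouplings(topoOf("OC[C@@H](C)C(O)=O")), 4L)
    expect_equal(countCouplings(topoOf("CC(C)CC(=O)C(O)=O")), 2L)
    # amide H-N-C-H vicinal coupling counts
    expect_equal(countCouplings(topoOf("CC(=O)NCC(O)=O")), 1L)
    # 4-bond olefin-to-methylene path of trans-aconitate does not
    expect_equal(countCouplings(topoOf("OC(=O)/C=C(\\CC(O)=O)C(O)=O")), 0L)
})

test_that("second-order flag fires on magnetic inequivalence only", {
    expect_equal(secondOrderFlag(topoOf("OC(=O)CC1=CC=CC=C1")), 1L)
    expect_equal(secondOrderFlag(topoOf("OC(=O)CC1=CC=C(O)C=C1")), 1L)
    expect_equal(secondOrderFlag(topoOf("CCO")), 0L)
    expect_equal(secondOrderFlag(topoOf("NCCS(O)(=O)=O")), 0L)
    expect_equal(secondOrderFlag(topoOf("NCCCCN")), 1L)
})

test_that("HSQC counting crosses proton classes with carbon orbits", {
    expect_equal(countHsqc(topoOf("OC(=O)CCC(O)=O")), 1L)
    expect_equal(countHsqc(topoOf("NCCS(O)(=O)=O")), 2L)
    # monosubstituted benzene: CH2 plus ortho/meta/para orbits
    expect_equal(countHsqc(topoOf("OC(=O)CC1=CC=CC=C1")), 4L)
    # diastereotopic methylene contributes two peaks
    expect_equal(countHsqc(topoOf("OC[C@@H](C)C(O)=O")), 4L)
})

test_that("HMBC counting matches the exhaustive pair-enumeration oracle", {
    expect_equal(countHmbc(topoOf("C")), 0L)
    # cross-methyl peak of trimethylamine is real and counted once
    expect_equal(countHmbc(topoOf("CN(C)C")), 1L)
    # frozen from the hand oracle: ketoleucine has 10 distinct pairs
    expect_equal(countHmbc(topoOf("CC(C)CC(=O)C(O)=O")), 10L)
    for (smi in c("CC(C)CC(=O)C(O)=O", "OC(=O)CC1=CC=CC=C1",
                  "NC(=N)NCC(O)=O", "OC(=O)CC(O)(CC(O)=O)C(O)=O",
                  "C[N+](C)(C)CCO")) {
        topo <- topoOf(smi)
        expect_equal(countHmbc(topo), hmbcOracle(topo), info = smi)
    }
})

test_that("theoretical profiles sum the anomeric forms", {
    fix <- cachedFixture()
    glc <- theoreticalProfile(fix[["d_glucose"]])
    expect_equal(glc@nShifts, 14L)
    expect_equal(bitsVector(levelBits(glc))[["1D"]], 42L)
    fuc <- theoreticalProfile(fix[["l_fucose"]])
    expect_equal(fuc@nShifts, 12L)
    # single-form molecule: profile equals the per-form counts
    ala <- theoreticalProfile(fix[["l_alanine"]])
    topo <- topoOf(fix[["l_alanine"]]@forms[1])
    expect_equal(ala@nShifts,
                 unname(countShiftsAndMultiplicities(topo)[1]))
    # mixed formulas across forms are rejected
    bad <- makeRecord("bad", c("CCO", "CC(O)=O"))
    expect_error(theoreticalProfile(bad), "different molecular formulas")
})

test_that("curated overrides replace the algorithmic profile", {
    ov <- makeRecord("ov", "CCO",
        overrides = new("SpectralFeatureCounts", nShifts = 5L,
                        nMultiplicities = 5L, nCouplings = 2L,
                        secondOrderFlag = 0L, nCosy = 2L, nHsqc = 3L,
                        nHmbc = 4L, provenance = "theoretical"))
    expect_equal(theoreticalProfile(ov)@nShifts, 5L)
})

test_that("level bits are cumulative sums with the documented identities", {
    hiba2 <- levelBits(theoreticalProfile(cachedFixture()[["hiba_2"]]))
    expect_equal(bitsVector(hiba2)[["1D"]], 2L)
    hiba3 <- levelBits(theoreticalProfile(cachedFixture()[["hiba_3"]]))
    expect_equal(bitsVector(hiba3)[["1D"]], 12L)
    zero <- levelBits(new("SpectralFeatureCounts", nShifts = 0L,
                          nMultiplicities = 0L, nCouplings = 0L,
                          secondOrderFlag = 0L, nCosy = 0L, nHsqc = 0L,
                          nHmbc = 0L, provenance = "observed"))
    expect_equal(unname(bitsVector(zero)), rep(0L, 4L))
})

test_that("monotonicity and the COSY=couplings identity hold cohort-wide", {
    for (theo in cachedTheoreticals()) {
        v <- bitsVector(levelBits(theo))
        expect_false(is.unsorted(v))
        expect_equal(theo@nCosy, theo@nCouplings)
        expect_equal(theo@nMultiplicities, theo@nShifts)
    }
})

test_that("cohort-wide extremes match the study set", {
    prof <- cachedProfileTable()
    expect_equal(min(prof$bits_1d), 2L)
    expect_equal(max(prof$bits_1d), 42L)
    expect_equal(min(prof$bits_hsqc), 3L)
    chiral <- prof$n_stereocenters >= 1
    expect_gt(mean(prof$bits_hsqc[chiral]), mean(prof$bits_hsqc[!chiral]))
})
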