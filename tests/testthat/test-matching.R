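test_that("fucose observations match the database reference within tolerance", {
    obs <- cachedObservations()[["l_fucose"]]
    refs <- readReferences(system.file("extdata", "references_fucose.json",
                                       package = "nmrbits"))
    m <- matchFeatures(obs, refs[["l_fucose"]])
    expect_true(m$matchOk)
    expect_equal(m$nFailed, 0L)
    # the 0.01 ppm methyl and 0.17 ppm carbon deviations both pass
    rec <- m$records
    expect_true(rec$pass[rec$type == "1H" & rec$assignment == "CH3b"])
    expect_true(rec$pass[rec$type == "13C" & rec$assignment == "CH3b"])
    expect_equal(rec$delta[rec$type == "13C" & rec$assignment == "CH3b"],
                 0.17, tolerance = 1e-9)
    # boundary values (0.03 ppm, 0.5 ppm deltas) pass: "within +/-"
    expect_true(rec$pass[rec$type == "1H" & rec$assignment == "H1a"])
    expect_true(rec$pass[rec$type == "13C" & rec$assignment == "H1b"])
})

test_that("identical values match with zero delta", {
    obs <- observedFeatureSet("x",
        shifts = data.frame(ppm = 1.25, assignment = "a"))
    ref <- list(metabolite_id = "x", source = "test",
                shifts_h = data.frame(assignment = "a", ppm = 1.25))
    m <- matchFeatures(obs, ref)
    expect_equal(m$records$delta, 0)
    expect_true(m$matchOk)
})

test_that("match results are invariant to feature-list order", {
    refs <- readReferences(system.file("extdata", "references_fucose.json",
                                       package = "nmrbits"))
    obs <- cachedObservations()[["l_fucose"]]
    shuffled <- obs
    set.seed(11)
    shuffled@shifts <- shuffled@shifts[sample(nrow(shuffled@shifts)), ]
    a <- matchFeatures(obs, refs[["l_fucose"]])
    b <- matchFeatures(shuffled, refs[["l_fucose"]])
    key <- function(m) {
        r <- m$records[order(m$records$type, m$records$assignment), ]
        rownames(r) <- NULL
        r
    }
    expect_equal(key(a), key(b))
})

test_that("shrinking a tolerance never converts a fail into a pass", {
    set.seed(42)
    obs <- observedFeatureSet("x",
        shifts = data.frame(ppm = 1 + runif(12, -0.06, 0.06),
                            assignment = paste0("a", 1:12)))
    ref <- list(metabolite_id = "x", source = "test",
                shifts_h = data.frame(assignment = paste0("a", 1:12),
                                      ppm = rep(1, 12)))
    wide <- matchFeatures(obs, ref, matchTolerances(dH = 0.05))
    narrow <- matchFeatures(obs, ref, matchTolerances(dH = 0.02))
    passWide <- wide$records$assignment[wide$records$pass]
    passNarrow <- narrow$records$assignment[narrow$records$pass]
    expect_true(all(passNarrow %in% passWide))
    expect_gt(length(passWide), length(passNarrow))
})

test_that("unpaired observations are listed, empty comparisons error", {
    ref <- list(metabolite_id = "x", source = "test",
                shifts_h = data.frame(assignment = "a", ppm = 1.0))
    obs <- observedFeatureSet("x",
        shifts = data.frame(ppm = c(1.0, 2.0), assignment = c("a", "zz")))
    m <- matchFeatures(obs, ref)
    expect_equal(m$unpaired, "1H zz")
    expect_equal(m$nFailed, 0L)
    orphan <- observedFeatureSet("x",
        shifts = data.frame(ppm = 2.0, assignment = "zz"))
    expect_error(matchFeatures(orphan, ref), "no shared assignments")
})

test_that("coverage requires observations in every annotated fragment", {
    fix <- cachedFixture()
    obs <- cachedObservations()
    # carnitine: all information on the ammonium side only
    cov <- assessCoverage(obs[["l_carnitine"]], fix[["l_carnitine"]])
    expect_equal(cov$coverageFraction, 0.5)
    expect_false(cov$coverageOk)
    # single-fragment default: any observation covers the molecule
    cov2 <- assessCoverage(obs[["ketoleucine"]], fix[["ketoleucine"]])
    expect_equal(cov2$coverageFraction, 1)
    expect_true(cov2$coverageOk)
    # a two-part molecule with bits in both parts is fully covered
    pcg <- makeRecord("pcg", fix[["p_cresol_glucuronide"]]@forms,
        fragmentAnnotations = list(cresol = c("ArH", "CH3"),
                                   glucuronide = c("H1g", "H5g")))
    both <- observedFeatureSet("pcg",
        shifts = data.frame(ppm = c(7.1, 5.1), assignment = c("ArH", "H1g")))
    cov3 <- assessCoverage(both, pcg)
    expect_equal(cov3$coverageFraction, 1)
    expect_true(cov3$coverageOk)
    # labels outside the annotated molecule are an error
    stray <- observedFeatureSet("pcg",
        shifts = data.frame(ppm = 9.9, assignment = "nonsense"))
    expect_error(assessCoverage(stray, pcg), "outside")
})
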