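test_that("generators are bit-identical under a fixed seed", {
    sp <- sectionPhantomSpec(undulationAmplitude = 15, boundaryNoiseSd = 5,
                             samplingStep = 4, seed = 11L)
    a <- genSectionPhantom(sp)
    b <- genSectionPhantom(sp)
    expect_identical(lapply(traces(a$profile), slot, "vertices"),
                     lapply(traces(b$profile), slot, "vertices"))
    expect_identical(a$truth, b$truth)

    ts <- trabPhantomSpec("random_field", targetFraction = 0.4,
                          domainSize = c(1, 1), resolution = 0.02, seed = 3L)
    expect_identical(boneMask(genTrabPhantom2D(ts)$mask),
                     boneMask(genTrabPhantom2D(ts)$mask))
    t3 <- trabPhantomSpec("random_field", targetFraction = 0.4,
                          domainSize = c(0.6, 0.6, 0.6), resolution = 0.02,
                          seed = 3L)
    expect_identical(boneMask(genTrabPhantom3D(t3)$volume),
                     boneMask(genTrabPhantom3D(t3)$volume))

    cs <- cohortSpec(nPerGroup = 4, compartments = "MTP",
                     parameters = "Cg.Th", seed = 5L)
    expect_identical(genCohort(cs), genCohort(cs))
})

test_that("flat section phantom has flat-layer ground truth", {
    sp <- sectionPhantomSpec(layerMeans = c(nCg = 300, cCg = 120, SB = 350),
                             undulationAmplitude = 0, boundaryNoiseSd = 0,
                             samplingStep = 4)
    tr <- genSectionPhantom(sp)$truth
    expect_equal(tr$value[tr$parameter == "nCg.Th"], rep(300, 4))
    expect_equal(tr$value[tr$parameter == "Cg.Th"], rep(420, 4))
    expect_equal(tr$value[tr$parameter == "FI"], rep(1, 4))
})

test_that("sinusoidal surface ground-truth FI matches the quadrature oracle", {
    sp <- sectionPhantomSpec(undulationAmplitude = 20,
                             undulationWavelength = 200,
                             boundaryNoiseSd = 0, samplingStep = 1)
    tr <- genSectionPhantom(sp)$truth
    oracle <- sinusoidFIOracle(20, 200, 0, 2000)
    for (v in tr$value[tr$parameter == "FI"])
        expect_equal(v, oracle, tolerance = 1e-5)
})

test_that("impossible section specs and crossing boundaries are handled", {
    expect_error(sectionPhantomSpec(undulationWavelength = 1,
                                    samplingStep = 1), "twice the sampling")
    expect_error(sectionPhantomSpec(layerMeans = c(nCg = -1, cCg = 1,
                                                   SB = 1)), "> 0")
    # roughness much larger than the thinnest layer forces regeneration
    sp <- sectionPhantomSpec(layerMeans = c(nCg = 30, cCg = 10, SB = 30),
                             boundaryNoiseSd = 40, samplingStep = 4,
                             seed = 2L)
    w <- capture_warnings(ph <- genSectionPhantom(sp))
    expect_true(any(grepl("regenerating", w)))
    tr <- traces(ph$profile)
    expect_true(all(tr$surface@vertices[, 2] >= tr$tidemark@vertices[, 2]))
})

test_that("plate phantom truths follow t/(t+s)", {
    p1 <- genTrabPhantom2D(trabPhantomSpec("plates", t = 0.3, s = 0.3,
                                           domainSize = c(1.2, 1.2),
                                           resolution = 0.01))
    expect_equal(p1$truth$Tb.A, 50)
    p2 <- genTrabPhantom2D(trabPhantomSpec("plates", t = 0.1, s = 0.2,
                                           domainSize = c(1.5, 1.5),
                                           resolution = 0.01))
    expect_equal(p2$truth$Tb.A, 100 / 3, tolerance = 1e-9)
    expect_equal(tbArea(p2$mask), 100 / 3, tolerance = 0.02)
    expect_error(trabPhantomSpec("plates", t = 0.05, resolution = 0.05),
                 "unresolvable")
    expect_warning(trabPhantomSpec("plates", t = 0.12, resolution = 0.04),
                   "t/5")
})

test_that("random-field phantoms hit their target bone fraction", {
    p <- genTrabPhantom2D(trabPhantomSpec("random_field",
                                          targetFraction = 0.5,
                                          domainSize = c(4, 4),
                                          resolution = 0.01, seed = 7L))
    expect_equal(mean(boneMask(p$mask)), 0.5, tolerance = 0.01)
    expect_equal(p$truth$Tb.A, 50)
})

test_that("3D phantom closed forms: solid, plates, rods", {
    solid <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.2, s = 0,
                                              domainSize = c(0.4, 0.4, 0.4),
                                              resolution = 0.02))
    expect_equal(solid$truth$BV.TV, 100)
    expect_equal(bvTv(solid$volume), 100)

    pl <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.15, s = 0.30,
                                           domainSize = c(0.9, 0.9, 0.9),
                                           resolution = 0.01))
    expect_equal(pl$truth$BV.TV, 100 / 3, tolerance = 1e-9)
    expect_equal(pl$truth$Tb.Th, 0.15)
    expect_equal(pl$truth$Tb.Sp, 0.30)

    rod <- genTrabPhantom3D(trabPhantomSpec("rods", rodRadius = 0.1,
                                            rodPitch = 0.5,
                                            domainSize = c(1, 1, 0.5),
                                            resolution = 0.01))
    expect_equal(rod$truth$BV.TV, 12.57, tolerance = 1e-3)
    expect_equal(rod$truth$Tb.Th, 0.2)
})

test_that("rendered plate bone fraction converges to truth under refinement", {
    # period deliberately not divisible by the resolutions
    errs <- vapply(c(0.02, 0.01, 0.005), function(h) {
        p <- genTrabPhantom2D(trabPhantomSpec("plates", t = 0.13, s = 0.29,
                                              domainSize = c(1.26, 1.26),
                                              resolution = h))
        abs(tbArea(p$mask) - p$truth$Tb.A)
    }, numeric(1))
    expect_lt(errs[2], errs[1] + 1e-9)
    expect_lt(errs[3], errs[2] + 1e-9)
})

test_that("cohort generator honours design, truncation and parameterization", {
    cs <- cohortSpec(nPerGroup = c(SHAM = 7, CONT = 8, RIS = 8), seed = 1L)
    co <- genCohort(cs)
    cells <- nrow(unique(co[, c("joint", "compartment", "zone",
                                "parameter")]))
    counts <- table(co$group)
    expect_equal(as.vector(counts[c("SHAM", "CONT", "RIS")]),
                 c(7, 8, 8) * cells)
    expect_true(all(co$value > 0))

    # sd = 0 reproduces the configured means exactly
    pr <- cohortDefaults()
    pr$sd <- 0
    czero <- genCohort(cohortSpec(nPerGroup = 2, params = pr, seed = 2L))
    key <- paste(czero$joint, czero$group, czero$zone, czero$compartment,
                 czero$parameter)
    pkey <- paste(pr$joint, pr$group, pr$zone, pr$compartment, pr$parameter)
    expect_equal(czero$value, pr$mean[match(key, pkey)])

    # a requested but unparameterized cell is rejected with its key
    expect_error(genCohort(cohortSpec(parameters = "Nonexistent")),
                 "Nonexistent")
})

test_that("per-cell cohort means stay near the configured means", {
    # sampling-theory check: cell sample means of n=8 draws lie within
    # 3 sd/sqrt(8) of the configured mean in almost every cell (truncation
    # at zero shifts the handful of cells whose printed CV is extreme)
    fracs <- vapply(1:20, function(s) {
        co <- genCohort(cohortSpec(nPerGroup = 8, seed = s))
        co$zone[is.na(co$zone)] <- "none"
        ag <- aggregate(value ~ joint + group + compartment + zone +
                            parameter, co, mean)
        pr <- cohortDefaults()
        pr$zone[is.na(pr$zone)] <- "none"
        key <- paste(ag$joint, ag$group, ag$compartment, ag$zone,
                     ag$parameter)
        pkey <- paste(pr$joint, pr$group, pr$compartment, pr$zone,
                      pr$parameter)
        i <- match(key, pkey)
        mean(abs(ag$value - pr$mean[i]) <= 3 * pr$sd[i] / sqrt(8))
    }, numeric(1))
    expect_gte(mean(fracs), 0.98)
})
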