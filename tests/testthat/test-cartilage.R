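test_that("zoned ROI follows the surface chord and common support", {
    p <- flatProfile()
    roi <- defineROI(p)
    expect_equal(chordWidth(roi), 8000)
    expect_equal(zoneBreaks(roi), c(0, 2000, 4000, 6000, 8000))

    # common support [100, 7900]: surface wider than the deep boundaries
    tr <- traces(p)
    tr$tidemark <- flatTrace("tidemark", 470, 100, 7900)
    tr$cement_line <- flatTrace("cement_line", 350, 100, 7900)
    tr$trab_junction <- flatTrace("trab_junction", 0, 100, 7900)
    p2 <- new("SectionProfile", traces = tr, compartment = "MTP",
              specimen = "S", group = "CONT", joint = "OA")
    roi2 <- defineROI(p2)
    expect_equal(chordWidth(roi2), 7800)
    expect_equal(diff(zoneBreaks(roi2)), rep(1950, 4))

    p3 <- new("SectionProfile", traces = tr["tidemark"],
              compartment = "MTP", specimen = "S", group = "CONT",
              joint = "OA")
    expect_error(defineROI(p3), "surface")
})

test_that("parallel boundaries give the exact separation in every zone", {
    p <- flatProfile(nCg = 300, cCg = 120, SB = 350)
    roi <- defineROI(p)
    th <- meanThickness(p, "surface", "tidemark", roi)
    expect_equal(th$value, rep(300, 4), tolerance = 1e-12)
    expect_equal(th$nUsed, rep(100L, 4))
    expect_equal(th$nExcluded, rep(0L, 4))
    expect_error(meanThickness(p, "tidemark", "surface", roi), "not above")
})

test_that("a sinusoidal surface averages out over whole periods", {
    # amplitude 20, wavelength 200: each 2000 um zone holds 10 full periods
    sp <- sectionPhantomSpec(layerMeans = c(nCg = 300, cCg = 120, SB = 350),
                             undulationAmplitude = 20,
                             undulationWavelength = 200,
                             boundaryNoiseSd = 0, samplingStep = 1)
    ph <- genSectionPhantom(sp)
    th <- meanThickness(ph$profile, "surface", "tidemark", ph$roi)
    expect_equal(th$value, rep(300, 4), tolerance = 0.1 / 300)
})

test_that("measured thickness recovers phantom ground truth within 1%", {
    sp <- sectionPhantomSpec(undulationAmplitude = 25,
                             undulationWavelength = 350,
                             boundaryNoiseSd = 5, samplingStep = 1,
                             seed = 21L)
    ph <- genSectionPhantom(sp)
    m <- measureSection(ph$profile, ph$roi, nRays = 100)
    for (p in c("nCg.Th", "cCg.Th", "SB.Th", "Cg.Th")) {
        got <- m$value[m$parameter == p]
        want <- ph$truth$value[ph$truth$parameter == p]
        expect_equal(got, want, tolerance = 0.01)
    }
})

test_that("total cartilage thickness is the exact layer sum, NA-propagating", {
    expect_equal(totalCartilageThickness(308.90, 155.99), 464.89)
    expect_equal(totalCartilageThickness(0, 5), 5)
    expect_true(is.na(totalCartilageThickness(NA_real_, 5)))
    ph <- genSectionPhantom(sectionPhantomSpec(boundaryNoiseSd = 6,
                                               samplingStep = 2, seed = 3L))
    roi <- ph$roi
    ncg <- meanThickness(ph$profile, "surface", "tidemark", roi)
    ccg <- meanThickness(ph$profile, "tidemark", "cement_line", roi)
    cg <- totalCartilageThickness(ncg, ccg)
    expect_identical(cg$value, ncg$value + ccg$value)
})

test_that("fibrillation index is 1 for straight surfaces and matches analytic arclengths", {
    p <- flatProfile()
    fi <- fibrillationIndex(p, defineROI(p))
    expect_identical(fi$FI, rep(1, 4))
    expect_equal(fi$excess, rep(0, 4))

    # semicircular notch of radius 100 um in a 1000 um zone:
    # L = 1000 - 200 + 100 pi, FI = 1.1142
    np <- notchedProfile(r = 100, cx = 500, x0 = 0, x1 = 1000)
    roi <- new("ZonedROI", p0 = c(0, 800), p1 = c(1000, 800), width = 1000,
               breaks = c(0, 1000))
    fin <- fibrillationIndex(np, roi)
    expect_equal(fin$L, 800 + 100 * pi, tolerance = 1e-5)
    expect_equal(fin$FI, 1.1142, tolerance = 1e-3)

    sp <- sectionPhantomSpec(undulationAmplitude = 20,
                             undulationWavelength = 200,
                             boundaryNoiseSd = 0, samplingStep = 1)
    ph <- genSectionPhantom(sp)
    fis <- fibrillationIndex(ph$profile, ph$roi)
    expect_equal(fis$FI, rep(sinusoidFIOracle(20, 200, 0, 2000), 4),
                 tolerance = 1e-3)
})

test_that("FI increases strictly with undulation amplitude", {
    fis <- vapply(c(5, 10, 20, 40), function(a) {
        ph <- genSectionPhantom(sectionPhantomSpec(undulationAmplitude = a,
                                                   undulationWavelength = 200,
                                                   boundaryNoiseSd = 0,
                                                   samplingStep = 1))
        fibrillationIndex(ph$profile, ph$roi)$FI[1]
    }, numeric(1))
    expect_true(all(diff(fis) > 0))
})

test_that("measurements are invariant under rigid motion of the traces", {
    sp <- sectionPhantomSpec(undulationAmplitude = 20,
                             undulationWavelength = 400,
                             boundaryNoiseSd = 3, samplingStep = 2,
                             seed = 9L)
    ph <- genSectionPhantom(sp)
    m0 <- measureSection(ph$profile, nRays = 60)
    pR <- transformProfile(ph$profile, 30, c(1500, -700))
    mR <- measureSection(pR, nRays = 60)
    expect_equal(mR$value, m0$value, tolerance = 1e-9)
})

test_that("refinement of rays and vertices changes results below the budget", {
    sp <- function(step) sectionPhantomSpec(undulationAmplitude = 25,
                                            undulationWavelength = 350,
                                            boundaryNoiseSd = 0,
                                            samplingStep = step)
    v <- function(step, rays) {
        ph <- genSectionPhantom(sp(step))
        m <- measureSection(ph$profile, ph$roi, nRays = rays)
        m$value
    }
    d1 <- max(abs(v(4, 50) - v(2, 100)))
    d2 <- max(abs(v(2, 100) - v(1, 200)))
    expect_lt(d2, d1 + 1e-9)
    expect_lt(d2, 0.2)
})

test_that("rays that miss a boundary are excluded, counted and can void a zone", {
    # tidemark only covers the left 40% of the section
    tr <- traces(flatProfile())
    tr$tidemark <- flatTrace("tidemark", 470, 0, 3200)
    p <- new("SectionProfile", traces = tr, compartment = "MTP",
             specimen = "S", group = "CONT", joint = "OA")
    roi <- defineROI(flatProfile())   # full-width ROI from complete geometry
    w <- capture_warnings(th <- meanThickness(p, "surface", "tidemark", roi,
                                              nRays = 50))
    expect_true(any(grepl("unmeasurable", w)))
    expect_equal(th$value[1], 300, tolerance = 1e-12)
    expect_true(is.na(th$value[3]) && is.na(th$value[4]))
    expect_equal(th$nExcluded[4], 50L)
})
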