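solidVolume <- function(n = 40, h = 0.05, value = TRUE, site = "tibia") {
    new("TrabVolume3D", vol = array(value, c(n, n, n)), voxelSize = h,
        origin = c(0, 0, 0), site = site)
}

test_that("VOI extraction matches the analytic cylinder volume", {
    vol <- new("TrabVolume3D", vol = array(TRUE, c(140, 140, 140)),
               voxelSize = 0.025, origin = c(0, 0, 0), site = "femur")
    voi <- cylVOI(c(1.75, 1.75, 1.75), site = "femur")   # d 2.5, depth 2.5
    reg <- extractVOI(vol, voi)
    expect_equal(sum(reg@inside) * 0.025^3, pi * 1.25^2 * 2.5,
                 tolerance = 0.01)
    expect_equal(bvTv(reg), 100)

    expect_error(extractVOI(vol, cylVOI(c(0.5, 1.75, 1.75),
                                        site = "femur")),
                 "outside the volume")
})

test_that("BV/TV handles empty, solid and plate-phantom inputs", {
    expect_warning(v0 <- bvTv(solidVolume(20, value = FALSE)), "no bone")
    expect_equal(v0, 0)
    expect_equal(bvTv(solidVolume(20)), 100)
    pl <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.15, s = 0.30,
                                           domainSize = c(0.9, 0.9, 0.9),
                                           resolution = 0.01))
    expect_equal(bvTv(pl$volume), pl$truth$BV.TV, tolerance = 0.01)
})

test_that("maximal-sphere thickness recovers slabs, rods and plate gaps", {
    # single slab, 0.20 mm thick at 10 um voxels
    vol <- array(FALSE, c(60, 60, 60))
    vol[, , 21:40] <- TRUE
    slab <- new("TrabVolume3D", vol = vol, voxelSize = 0.01,
                origin = c(0, 0, 0), site = "tibia")
    expect_equal(as.numeric(localThickness(slab, "bone")), 0.20,
                 tolerance = 0.1)   # one-voxel convention: 0.19

    rod <- genTrabPhantom3D(trabPhantomSpec("rods", rodRadius = 0.1,
                                            rodPitch = 0.5,
                                            domainSize = c(0.5, 0.5, 0.5),
                                            resolution = 0.01))
    expect_lt(abs(as.numeric(localThickness(rod$volume, "bone")) - 0.20),
              0.0101)   # one voxel

    pl <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.15, s = 0.30,
                                           domainSize = c(0.9, 0.9, 0.9),
                                           resolution = 0.01))
    tbth <- localThickness(pl$volume, "bone")
    tbsp <- localThickness(pl$volume, "marrow")
    expect_lt(abs(as.numeric(tbth) - 0.15), 0.011)
    expect_lt(abs(as.numeric(tbsp) - 0.30), 0.011)

    expect_warning(
        na <- localThickness(solidVolume(10), "marrow"), "empty")
    expect_true(is.na(as.numeric(na)))
})

test_that("plate-model Tb.N reproduces the plate frequency", {
    pl <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.15, s = 0.30,
                                           domainSize = c(0.9, 0.9, 0.9),
                                           resolution = 0.01))
    bv <- bvTv(pl$volume)
    th <- as.numeric(localThickness(pl$volume, "bone"))
    expect_equal(tbN(bv, th), 1 / 0.45, tolerance = 0.02)
    expect_equal(tbN(100, 1.5), 1 / 1.5)
    expect_equal(tbN(0, 0.2), 0)
    expect_true(is.na(tbN(50, 0)))
    expect_equal(tbN(NA, 0.2, 0.3, method = "inverse"), 2)
})

test_that("tilting plates changes maximal-sphere thickness by < 5%", {
    t0 <- as.numeric(localThickness(genTrabPhantom3D(
        trabPhantomSpec("plates", t = 0.3, s = 0.3, orientation = 0,
                        domainSize = c(1.2, 1.2, 1.2),
                        resolution = 0.01))$volume, "bone"))
    t30 <- as.numeric(localThickness(genTrabPhantom3D(
        trabPhantomSpec("plates", t = 0.3, s = 0.3, orientation = 30,
                        domainSize = c(1.2, 1.2, 1.2),
                        resolution = 0.01))$volume, "bone"))
    expect_lt(abs(t30 - t0) / t0, 0.05)
})

test_that("central-plane sections obey the Delesse principle", {
    # plates are translation-invariant along z: every plane matches exactly
    pl <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.15, s = 0.30,
                                           domainSize = c(0.9, 0.9, 0.9),
                                           resolution = 0.01))
    bvp <- bvTv(pl$volume)
    for (k in round(seq(5, 85, length.out = 10)))
        expect_equal(100 * mean(boneMask(pl$volume)[, , k]), bvp,
                     tolerance = 1e-12)

    # stationary random field: plane fractions scatter around BV/TV
    ph <- genTrabPhantom3D(trabPhantomSpec("random_field",
                                           targetFraction = 0.45,
                                           correlationLength = 0.12,
                                           domainSize = c(3.2, 3.2, 2.0),
                                           resolution = 0.04, seed = 4L),
                           site = "tibia")
    bv <- bvTv(ph$volume)
    fracs <- vapply(round(seq(3, 48, length.out = 16)), function(k)
        100 * mean(boneMask(ph$volume)[, , k]), numeric(1))
    expect_equal(mean(fracs), bv, tolerance = 0.08)

    solid <- solidVolume(80, 0.04)
    sec <- centralPlaneSection(solid, cylVOI(c(1.6, 1.6, 1.6),
                                             site = "tibia"))
    expect_true(all(boneMask(sec)))
    expect_error(centralPlaneSection(solid, cylVOI(c(1.6, 1.6, 9),
                                                   site = "tibia")),
                 "outside")
})

test_that("measureVOI returns the four indices with tags", {
    pl <- genTrabPhantom3D(trabPhantomSpec("plates", t = 0.2, s = 0.3,
                                           domainSize = c(3.0, 3.0, 2.0),
                                           resolution = 0.02))
    reg <- extractVOI(pl$volume, cylVOI(c(1.5, 1.5, 1.0), site = "tibia",
                                        side = "lateral"))
    res <- measureVOI(reg)
    expect_named(res, c("BV.TV", "Tb.Th", "Tb.Sp", "Tb.N", "position",
                        "side"))
    expect_equal(res$BV.TV, 40, tolerance = 0.05)
    # the cylinder wall is boundary for in-VOI spheres, which biases Tb.Th
    # mildly low near the wall; the recovery is still within ~15%
    expect_equal(res$Tb.Th, 0.2, tolerance = 0.15)
    expect_equal(res$side, "lateral")
})
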