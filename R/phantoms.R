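#' Section phantom specification
#'
#' Parameters of a synthetic traced section: flat anatomical layers
#' (non-calcified cartilage, calcified cartilage, subchondral plate) under a
#' sinusoidally undulating articular surface, with optional smooth seeded
#' roughness on every boundary. The emitted polylines are the generating
#' object, so the analytic ground truth (per-zone layer thickness and surface
#' arclength) is computed from them exactly, never from a rendering.
#'
#' @param roiWidth chord width of the section, um
#' @param layerMeans named numeric: mean thickness of `nCg`, `cCg`, `SB`, um
#' @param undulationAmplitude amplitude of the surface sinusoid, um
#' @param undulationWavelength wavelength of the surface sinusoid, um
#' @param boundaryNoiseSd pointwise sd of the smooth roughness added to every
#'   boundary, um
#' @param noiseCorrelation correlation length of the roughness, um; roughness
#'   is drawn at knots this far apart and spline-interpolated, which keeps
#'   the surface rectifiable at histological scales
#' @param samplingStep vertex spacing of the emitted polylines, um
#' @param seed integer seed; fixed seed gives bit-identical output
#' @return a validated spec (list) for [genSectionPhantom()]
#' @export
sectionPhantomSpec <- function(roiWidth = 8000,
                               layerMeans = c(nCg = 400, cCg = 120, SB = 350),
                               undulationAmplitude = 20,
                               undulationWavelength = 400,
                               boundaryNoiseSd = 0,
                               noiseCorrelation = 200,
                               samplingStep = 1,
                               seed = 1L) {
    stopifnot(roiWidth > 0, samplingStep > 0,
              undulationAmplitude >= 0, undulationWavelength > 0,
              boundaryNoiseSd >= 0, noiseCorrelation > 0)
    if (!all(c("nCg", "cCg", "SB") %in% names(layerMeans)))
        stop("layerMeans must name nCg, cCg and SB")
    if (any(layerMeans <= 0)) stop("all layer means must be > 0")
    if (undulationWavelength <= 2 * samplingStep)
        stop("undulationWavelength must exceed twice the sampling step")
    structure(list(roiWidth = roiWidth, layerMeans = layerMeans,
                   undulationAmplitude = undulationAmplitude,
                   undulationWavelength = undulationWavelength,
                   boundaryNoiseSd = boundaryNoiseSd,
                   noiseCorrelation = noiseCorrelation,
                   samplingStep = samplingStep, seed = as.integer(seed)),
              class = "SectionPhantomSpec")
}

# smooth seeded roughness: gaussian draws at coarse knots, natural-spline
# interpolated to the sampling grid
.roughness <- function(x, sd, corr) {
    if (sd == 0) return(numeric(length(x)))
    knots <- seq(min(x), max(x) + corr, by = corr)
    stats::spline(knots, rnorm(length(knots), 0, sd), xout = x)$y
}

#' Generate a synthetic traced section with analytic ground truth
#'
#' Emits the four boundary polylines of a section profile together with the
#' exact per-zone ground truth computed from those same polylines: layer
#' thicknesses as exact integrals of the piecewise-linear boundary gaps
#' measured perpendicular to the ROI chord, and the fibrillation index as the
#' exact polyline arclength over the zone width. If boundary roughness makes
#' adjacent boundaries cross, the phantom is regenerated with the roughness
#' halved (with a warning), up to five times.
#'
#' @param spec a [sectionPhantomSpec()]
#' @param compartment,specimen,group,joint metadata for the emitted profile
#' @return list with `profile` ([SectionProfile-class]), `roi`
#'   ([ZonedROI-class]) and `truth` (data.frame: zone, parameter, value)
#' @export
genSectionPhantom <- function(spec, compartment = "MTP",
                              specimen = "PHANTOM-1", group = "CONT",
                              joint = "OA") {
    stopifnot(inherits(spec, "SectionPhantomSpec"))
    build <- function(noiseSd) {
        x <- seq(0, spec$roiWidth, by = spec$samplingStep)
        if (x[length(x)] < spec$roiWidth) x <- c(x, spec$roiWidth)
        base <- 0
        yj <- base + .roughness(x, noiseSd, spec$noiseCorrelation)
        yc <- base + spec$layerMeans[["SB"]] +
            .roughness(x, noiseSd, spec$noiseCorrelation)
        yt <- base + spec$layerMeans[["SB"]] + spec$layerMeans[["cCg"]] +
            .roughness(x, noiseSd, spec$noiseCorrelation)
        ys <- base + sum(spec$layerMeans) +
            spec$undulationAmplitude *
                sin(2 * pi * x / spec$undulationWavelength) +
            .roughness(x, noiseSd, spec$noiseCorrelation)
        list(x = x, surface = ys, tidemark = yt, cement_line = yc,
             trab_junction = yj)
    }
    noiseSd <- spec$boundaryNoiseSd
    b <- withr::with_seed(spec$seed, {
        for (attempt in seq_len(6)) {
            cand <- build(noiseSd)
            ok <- all(cand$surface >= cand$tidemark) &&
                all(cand$tidemark >= cand$cement_line) &&
                all(cand$cement_line >= cand$trab_junction)
            if (ok) break
            if (attempt == 6)
                stop("boundaries still cross after shrinking the roughness; ",
                     "the spec is not realisable")
            warning("boundaries crossed after noise injection; ",
                    "regenerating with roughness sd ", noiseSd / 2)
            noiseSd <- noiseSd / 2
        }
        cand
    })
    mk <- function(role, y)
        new("BoundaryTrace", role = role,
            vertices = unname(cbind(b$x, y)))
    profile <- new("SectionProfile",
        traces = list(surface = mk("surface", b$surface),
                      tidemark = mk("tidemark", b$tidemark),
                      cement_line = mk("cement_line", b$cement_line),
                      trab_junction = mk("trab_junction", b$trab_junction)),
        compartment = compartment, specimen = specimen, group = group,
        joint = joint)
    roi <- defineROI(profile)
    truth <- .sectionTruth(profile, roi)
    list(profile = profile, roi = roi, truth = truth)
}

# exact ground truth from the generating polylines, in the chord frame used
# by the measurements
.sectionTruth <- function(profile, roi) {
    tr <- lapply(traces(profile),
                 function(t) .chordFrame(t@vertices, roi@p0, roi@p1))
    br <- roi@breaks
    nz <- length(br) - 1L
    pars <- c("nCg.Th", "cCg.Th", "Cg.Th", "SB.Th", "FI")
    out <- expand.grid(zone = .ZONES[seq_len(nz)], parameter = pars,
                       value = NA_real_, stringsAsFactors = FALSE)
    for (z in seq_len(nz)) {
        x0 <- br[z]; x1 <- br[z + 1]
        ncg <- .meanGap(tr$surface, tr$tidemark, x0, x1)
        ccg <- .meanGap(tr$tidemark, tr$cement_line, x0, x1)
        sb <- .meanGap(tr$cement_line, tr$trab_junction, x0, x1)
        fi <- .arclength(.clipPolyline(tr$surface, x0, x1)) / (x1 - x0)
        vals <- c(ncg, ccg, ncg + ccg, sb, fi)
        for (p in seq_along(pars))
            out$value[out$zone == .ZONES[z] & out$parameter == pars[p]] <-
                vals[p]
    }
    out
}

#' Trabecular phantom specification
#'
#' Geometry of a synthetic trabecular structure with closed-form ground
#' truth: parallel plates (thickness `t`, spacing `s`, so bone fraction
#' `t/(t+s)`), axis-aligned rods on a square lattice (bone fraction
#' `pi r^2 / pitch^2`, thickness `2r`), or a thresholded smooth Gaussian
#' random field with a prescribed bone fraction.
#'
#' @param kind `"plates"`, `"rods"` or `"random_field"`
#' @param t,s plate thickness and spacing, mm
#' @param orientation plate tilt in degrees (rotation of the plate normal
#'   away from +x, about the y axis in 3D)
#' @param rodRadius,rodPitch rod geometry, mm (rods run along z)
#' @param targetFraction bone fraction of a random field, in (0, 1)
#' @param correlationLength transverse correlation length of the random
#'   field, mm; the default (0.08 mm) puts the thresholded feature widths at
#'   the 0.1-0.16 mm scale of rabbit subchondral trabeculae
#' @param anisotropy axial elongation of the field correlation (z relative
#'   to x/y, 3D only); subchondral trabeculae are preferentially oriented
#'   along the loading axis, so the default field is 2.5x longer axially
#' @param domainSize physical extent, mm: length 2 (2D) or 3 (3D)
#' @param resolution pixel/voxel edge, mm
#' @param seed integer seed
#' @return a validated spec (list) for [genTrabPhantom2D()] /
#'   [genTrabPhantom3D()]
#' @export
trabPhantomSpec <- function(kind = c("plates", "rods", "random_field"),
                            t = 0.15, s = 0.30, orientation = 0,
                            rodRadius = 0.1, rodPitch = 0.5,
                            targetFraction = 0.5, correlationLength = 0.08,
                            anisotropy = 2.5,
                            domainSize = c(1.8, 1.8, 1.8),
                            resolution = 0.01, seed = 1L) {
    kind <- match.arg(kind)
    stopifnot(resolution > 0, all(domainSize > 0))
    if (kind == "plates") {
        stopifnot(t > 0, s >= 0)
        if (resolution >= t)
            stop("resolution >= plate thickness: structure unresolvable")
        if (resolution > t / 5)
            warning("resolution coarser than t/5; analytic recovery will be ",
                    "degraded")
    }
    if (kind == "rods") {
        stopifnot(rodRadius > 0, rodPitch > 2 * rodRadius)
        if (resolution >= 2 * rodRadius)
            stop("resolution >= rod diameter: structure unresolvable")
    }
    if (kind == "random_field")
        stopifnot(targetFraction > 0, targetFraction < 1,
                  correlationLength > 0, anisotropy > 0)
    structure(list(kind = kind, t = t, s = s, orientation = orientation,
                   rodRadius = rodRadius, rodPitch = rodPitch,
                   targetFraction = targetFraction,
                   correlationLength = correlationLength,
                   anisotropy = anisotropy,
                   domainSize = domainSize, resolution = resolution,
                   seed = as.integer(seed)),
              class = "TrabPhantomSpec")
}

# separable gaussian blur of a matrix/3D array with circular wrapping (keeps
# the field stationary); sigma per axis in grid units. The kernel is clipped
# to the axis length when the domain is only a few correlation lengths wide.
.gaussBlur <- function(a, sigma) {
    blur1 <- function(m, s) {
        half <- max(1L, min(ceiling(3 * s), floor((nrow(m) - 1) / 2)))
        k <- exp(-0.5 * ((-half:half) / s)^2)
        k <- k / sum(k)
        # column-wise circular convolution of a matrix
        as.matrix(stats::filter(m, k, method = "convolution", sides = 2,
                                circular = TRUE))
    }
    d <- dim(a)
    sigma <- rep_len(sigma, length(d))
    if (length(d) == 2) {
        a <- blur1(a, sigma[1])
        a <- t(blur1(t(a), sigma[2]))
        return(a)
    }
    # 3D: blur along each axis by reshaping so the axis runs down columns
    for (ax in 1:3) {
        perm <- c(ax, setdiff(1:3, ax))
        ap <- aperm(a, perm)
        dp <- dim(ap)
        m <- blur1(matrix(ap, nrow = dp[1]), sigma[ax])
        a <- aperm(array(m, dp), order(perm))
    }
    a
}

.plateField <- function(coords, t, s, orientationDeg) {
    th <- orientationDeg * pi / 180
    proj <- coords$x * cos(th) +
        (if (is.null(coords$z)) 0 else coords$z) * sin(th)
    (proj %% (t + s)) < t
}

#' Generate a 2D trabecular phantom
#'
#' Renders the spec geometry on a pixel grid (pixel-centre inclusion test)
#' and returns the mask together with the closed-form ground truth computed
#' from the generating parameters, never from the raster.
#'
#' @param spec a [trabPhantomSpec()] with a length-2 `domainSize`
#' @param site `"femur"` or `"tibia"` (ROI convention tag)
#' @return list with `mask` ([TrabMask2D-class]) and `truth` (named list:
#'   `Tb.A` percent, plus `Tb.Th`/`Tb.Sp` mm for plates)
#' @export
genTrabPhantom2D <- function(spec, site = "tibia") {
    stopifnot(inherits(spec, "TrabPhantomSpec"))
    if (length(spec$domainSize) != 2)
        stop("2D phantom needs a length-2 domainSize")
    if (spec$kind == "rods")
        stop("rod phantoms are 3D; use genTrabPhantom3D")
    h <- spec$resolution
    nx <- round(spec$domainSize[1] / h)
    ny <- round(spec$domainSize[2] / h)
    xs <- (seq_len(nx) - 0.5) * h
    ys <- (seq_len(ny) - 0.5) * h
    if (spec$kind == "plates") {
        cx <- matrix(xs, nrow = ny, ncol = nx, byrow = TRUE)
        cy <- matrix(ys, nrow = ny, ncol = nx)
        th <- spec$orientation * pi / 180
        proj <- cx * cos(th) + cy * sin(th)
        # pattern starts with half a marrow gap so no plate is cut by the
        # domain edge along the plate normal
        off <- (proj - spec$s / 2) %% (spec$t + spec$s)
        mask <- off < spec$t
        truth <- list(Tb.A = 100 * spec$t / (spec$t + spec$s),
                      Tb.Th = spec$t, Tb.Sp = spec$s)
    } else {
        field <- withr::with_seed(spec$seed, matrix(rnorm(ny * nx), ny, nx))
        field <- .gaussBlur(field, spec$correlationLength / h)
        mask <- field >= quantile(field, 1 - spec$targetFraction)
        truth <- list(Tb.A = 100 * spec$targetFraction)
    }
    list(mask = new("TrabMask2D", mask = mask, pixelSize = h, site = site),
         truth = truth)
}

#' Generate a 3D trabecular phantom
#'
#' As [genTrabPhantom2D()] but on a voxel grid. Plates: `BV/TV =
#' 100 t/(t+s)`, `Tb.Th = t`, `Tb.Sp = s`. Rods on a square lattice along z:
#' `BV/TV = 100 pi r^2 / pitch^2`, `Tb.Th = 2r`. Random fields carry their
#' target bone fraction as truth.
#'
#' @param spec a [trabPhantomSpec()] with a length-3 `domainSize`
#' @param site `"femur"` or `"tibia"`
#' @return list with `volume` ([TrabVolume3D-class]) and `truth` (named list)
#' @export
genTrabPhantom3D <- function(spec, site = "tibia") {
    stopifnot(inherits(spec, "TrabPhantomSpec"))
    if (length(spec$domainSize) != 3)
        stop("3D phantom needs a length-3 domainSize")
    h <- spec$resolution
    nd <- round(spec$domainSize / h)
    xs <- (seq_len(nd[1]) - 0.5) * h
    ys <- (seq_len(nd[2]) - 0.5) * h
    zs <- (seq_len(nd[3]) - 0.5) * h
    if (spec$kind == "plates") {
        th <- spec$orientation * pi / 180
        proj <- outer(xs * cos(th), rep(0, nd[2]), "+")  # nx x ny
        vol <- array(FALSE, nd)
        period <- spec$t + spec$s
        # half a marrow gap first, so plates are interior to the domain
        for (k in seq_len(nd[3])) {
            pk <- proj + zs[k] * sin(th) - spec$s / 2
            vol[, , k] <- (pk %% period) < spec$t
        }
        truth <- list(BV.TV = 100 * spec$t / period, Tb.Th = spec$t,
                      Tb.Sp = spec$s, Tb.N = 1 / period)
    } else if (spec$kind == "rods") {
        r2 <- spec$rodRadius^2
        p <- spec$rodPitch
        # rod axes snapped to voxel centres so the lattice has no sub-voxel
        # offset relative to the grid
        cx <- (round(p / (2 * h)) + 0.5) * h
        dx <- (xs - cx + p / 2) %% p - p / 2
        dy <- (ys - cx + p / 2) %% p - p / 2
        sec <- outer(dx^2, dy^2, "+") <= r2
        vol <- array(sec, nd)
        truth <- list(BV.TV = 100 * pi * r2 / p^2,
                      Tb.Th = 2 * spec$rodRadius, Tb.N = 1 / p)
    } else {
        field <- withr::with_seed(spec$seed,
                                  array(rnorm(prod(nd)), nd))
        sig <- spec$correlationLength / h
        field <- .gaussBlur(field, c(sig, sig, sig * spec$anisotropy))
        vol <- field >= quantile(field, 1 - spec$targetFraction)
        truth <- list(BV.TV = 100 * spec$targetFraction)
    }
    list(volume = new("TrabVolume3D", vol = vol, voxelSize = h,
                      origin = c(0, 0, 0), site = site),
         truth = truth)
}
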