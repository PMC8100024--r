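#' Construct a cylindrical VOI
#'
#' @param center cylinder centre `c(x, y, z)` in mm
#' @param site `"femur"` (depth 2.5 mm) or `"tibia"` (depth 1.5 mm); sets the
#'   default depth
#' @param position `"anterior"`, `"central"` or `"posterior"`
#' @param side `"medial"` or `"lateral"`
#' @param diameter cylinder diameter, mm
#' @param depth cylinder depth along z, mm (default by site)
#' @return a [CylVOI-class]
#' @export
cylVOI <- function(center, site = "tibia", position = "central",
                   side = "medial", diameter = .VOI_DIAMETER,
                   depth = .VOI_DEPTH[[site]]) {
    new("CylVOI", center = as.numeric(center), diameter = diameter,
        depth = depth, position = position, side = side)
}

#' Place the three anatomical VOIs of a compartment
#'
#' Anterior, central and posterior cylinders along the anatomical y axis,
#' offset from a user-supplied compartment centre. The offsets are
#' configuration, not anatomy extracted from images.
#'
#' @param center compartment centre `c(x, y, z)` in mm
#' @param site `"femur"` or `"tibia"`
#' @param side `"medial"` or `"lateral"`
#' @param offset anterior/posterior displacement along y, mm
#' @return named list of three [CylVOI-class] objects
#' @export
anatomicalVOIs <- function(center, site = "tibia", side = "medial",
                           offset = 2.5) {
    list(anterior = cylVOI(center + c(0, -offset, 0), site, "anterior", side),
         central = cylVOI(center, site, "central", side),
         posterior = cylVOI(center + c(0, offset, 0), site, "posterior",
                            side))
}

#' Extract a cylindrical VOI from a volume
#'
#' Voxel-centre inclusion test against the analytic cylinder. Voxels outside
#' the cylinder are excluded from both phases downstream (they act as
#' boundary for local-thickness measurements). A VOI that is not fully inside
#' the volume is rejected, reporting the contained fraction.
#'
#' @param volume a [TrabVolume3D-class]
#' @param voi a [CylVOI-class]
#' @return a [VoiRegion-class] on the VOI's bounding subgrid
#' @export
extractVOI <- function(volume, voi) {
    stopifnot(is(volume, "TrabVolume3D"), is(voi, "CylVOI"))
    h <- voxelSize(volume)
    d <- dim(volume@vol)
    ext <- volume@origin + c(0, 0, 0)
    hi <- volume@origin + d * h
    r <- voi@diameter / 2
    b0 <- voi@center - c(r, r, voi@depth / 2)
    b1 <- voi@center + c(r, r, voi@depth / 2)
    if (any(b0 < ext - 1e-9) || any(b1 > hi + 1e-9)) {
        clip0 <- pmax(b0, ext)
        clip1 <- pmin(b1, hi)
        frac <- if (any(clip1 <= clip0)) 0 else {
            # crude contained-volume fraction from the clipped bounding box
            prod(clip1 - clip0) / prod(b1 - b0)
        }
        stop(sprintf(
            "VOI extends outside the volume (about %.0f%% of its bounding box is inside)",
            100 * frac))
    }
    i0 <- pmax(1L, floor((b0 - ext) / h) + 1L)
    i1 <- pmin(d, ceiling((b1 - ext) / h))
    xs <- ext[1] + (seq(i0[1], i1[1]) - 0.5) * h
    ys <- ext[2] + (seq(i0[2], i1[2]) - 0.5) * h
    zs <- ext[3] + (seq(i0[3], i1[3]) - 0.5) * h
    inPlane <- outer((xs - voi@center[1])^2, (ys - voi@center[2])^2,
                     "+") <= r^2
    inZ <- abs(zs - voi@center[3]) <= voi@depth / 2
    inside <- array(FALSE, c(length(xs), length(ys), length(zs)))
    for (k in seq_along(zs)) if (inZ[k]) inside[, , k] <- inPlane
    sub <- volume@vol[seq(i0[1], i1[1]), seq(i0[2], i1[2]),
                      seq(i0[3], i1[3]), drop = FALSE]
    new("VoiRegion", bone = sub & inside, inside = inside,
        voxelSize = h, voi = voi)
}

#' @rdname bvTv
#' @export
setMethod("bvTv", "VoiRegion", function(x) {
    nin <- sum(x@inside)
    if (nin == 0) stop("VOI contains no voxels")
    v <- 100 * sum(x@bone & x@inside) / nin
    if (v == 0) warning("VOI contains no bone")
    v
})

#' @rdname bvTv
#' @export
setMethod("bvTv", "TrabVolume3D", function(x) {
    v <- 100 * mean(x@vol)
    if (v == 0) warning("volume contains no bone")
    v
})

#' @rdname bvTv
#' @export
setMethod("bvTv", "TrabMask2D", function(x) tbArea(x))

# guard: number of voxels next to each domain face to drop from the mean.
# The distance transform treats the faces as boundary, so sphere radii within
# one maximal radius of a face can be truncated; "auto" excludes exactly that
# margin (stereological guard zone). 0 keeps every voxel.
.localThickness <- function(phaseArr, h, guard = 0) {
    n <- sum(phaseArr)
    if (n == 0) {
        warning("phase is empty; thickness is missing")
        return(structure(NA_real_, sd = NA_real_, n = 0L))
    }
    d <- dim(phaseArr)
    th <- cpp_local_thickness(as.logical(phaseArr), d)
    if (identical(guard, "auto")) {
        d2 <- cpp_edt_sq(as.logical(phaseArr), d)
        guard <- ceiling(sqrt(max(d2[as.vector(phaseArr)])))
    }
    keep <- as.vector(phaseArr)
    if (guard > 0) {
        inner <- function(nn) {
            v <- rep(FALSE, nn)
            if (nn > 2 * guard) v[(guard + 1):(nn - guard)] <- TRUE
            v
        }
        guardArr <- array(FALSE, d)
        gx <- inner(d[1]); gy <- inner(d[2]); gz <- inner(d[3])
        if (any(gx) && any(gy) && any(gz))
            guardArr[gx, gy, gz] <- TRUE
        if (any(keep & as.vector(guardArr)))
            keep <- keep & as.vector(guardArr)
        else
            warning("guard margin leaves no phase voxels; using all")
    }
    thmm <- th[keep] * h
    structure(mean(thmm), sd = sd(thmm), n = sum(keep))
}

#' @rdname localThickness
#' @param guard voxels adjacent to each domain face excluded from the mean
#'   (`"auto"` excludes one maximal sphere radius, the default for whole
#'   volumes; in-VOI measurements default to 0 because the cylinder wall is
#'   already the analysis boundary)
#' @export
setMethod("localThickness", "TrabVolume3D",
          function(x, phase, guard = "auto") {
    phase <- match.arg(phase, c("bone", "marrow"))
    arr <- if (phase == "bone") x@vol else !x@vol
    .localThickness(arr, voxelSize(x), guard)
})

#' @rdname localThickness
#' @export
setMethod("localThickness", "VoiRegion", function(x, phase, guard = 0) {
    phase <- match.arg(phase, c("bone", "marrow"))
    arr <- if (phase == "bone") x@bone & x@inside else !x@bone & x@inside
    .localThickness(arr, voxelSize(x), guard)
})

#' Trabecular number from the plate model
#'
#' Parfitt's parallel-plate identity `Tb.N = (BV/TV) / Tb.Th` (with BV/TV as
#' a fraction); the alternative `1 / (Tb.Th + Tb.Sp)` is available when
#' `Tb.Sp` is supplied and `method = "inverse"`.
#'
#' @param bvtv bone volume fraction in percent
#' @param tbth trabecular thickness, mm
#' @param tbsp trabecular separation, mm (only for `method = "inverse"`)
#' @param method `"plate"` or `"inverse"`
#' @return Tb.N in 1/mm; `NA` when `tbth` is zero or missing
#' @export
tbN <- function(bvtv, tbth, tbsp = NULL, method = c("plate", "inverse")) {
    method <- match.arg(method)
    if (method == "inverse") {
        if (is.null(tbsp)) stop("method 'inverse' needs tbsp")
        den <- tbth + tbsp
        return(ifelse(is.na(den) | den <= 0, NA_real_, 1 / den))
    }
    ifelse(is.na(tbth) | tbth <= 0, NA_real_, (bvtv / 100) / tbth)
}

#' Extract the central VOI mid-plane as a 2D mask
#'
#' Cuts the volume at the axial mid-plane of the central VOI and crops the
#' rectangle of the 2D trabecular ROI convention around the VOI centre,
#' enabling coupled 2D/3D measurements on the same synthetic specimen.
#'
#' @param volume a [TrabVolume3D-class]
#' @param voi the central [CylVOI-class]
#' @param site ROI convention, defaults to the volume's site tag
#' @return a [TrabMask2D-class]
#' @export
centralPlaneSection <- function(volume, voi, site = siteTag(volume)) {
    stopifnot(is(volume, "TrabVolume3D"), is(voi, "CylVOI"))
    h <- voxelSize(volume)
    d <- dim(volume@vol)
    k <- round((voi@center[3] - volume@origin[3]) / h + 0.5)
    if (k < 1 || k > d[3]) stop("VOI mid-plane lies outside the volume")
    plane <- volume@vol[, , k]       # [x, y]
    roiSize <- .ROI_2D[[site]]
    npx <- round(roiSize[1] / h)
    npy <- round(roiSize[2] / h)
    cx <- (voi@center[1] - volume@origin[1]) / h
    cy <- (voi@center[2] - volume@origin[2]) / h
    j0 <- round(cx - npx / 2)
    i0 <- round(cy - npy / 2)
    if (j0 < 0 || i0 < 0 || j0 + npx > d[1] || i0 + npy > d[2])
        stop("2D ROI around the VOI centre exceeds the volume extent")
    crop <- plane[(j0 + 1):(j0 + npx), (i0 + 1):(i0 + npy), drop = FALSE]
    new("TrabMask2D", mask = t(crop), pixelSize = h, site = site)
}

#' Measure all 3D parameters of one VOI
#'
#' @param region a [VoiRegion-class]
#' @return one-row data.frame: BV.TV (%), Tb.Th (mm), Tb.Sp (mm), Tb.N
#'   (1/mm), position, side
#' @export
measureVOI <- function(region) {
    stopifnot(is(region, "VoiRegion"))
    bv <- bvTv(region)
    th <- localThickness(region, "bone")
    sp <- localThickness(region, "marrow")
    data.frame(BV.TV = bv, Tb.Th = as.numeric(th), Tb.Sp = as.numeric(sp),
               Tb.N = tbN(bv, as.numeric(th)),
               position = region@voi@position, side = region@voi@side)
}
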