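#' Define the zoned region of interest of a section
#'
#' The ROI chord is the straight segment joining the surface trace's
#' endpoints restricted to the common x-support of all four boundaries; it is
#' divided into four contiguous zones of equal width (Z1..Z4). All thickness
#' rays and the fibrillation index are evaluated against this chord.
#'
#' @param profile a [SectionProfile-class] carrying all four boundaries
#' @param nZones number of equal zones (four in the standard protocol)
#' @return a [ZonedROI-class]
#' @export
defineROI <- function(profile, nZones = 4L) {
    stopifnot(is(profile, "SectionProfile"))
    tr <- traces(profile)
    missingRoles <- setdiff(.ROLES, names(tr))
    if (length(missingRoles))
        stop("profile is missing trace(s): ",
             paste(missingRoles, collapse = ", "))
    # the common support is measured along the chord direction (not raw x),
    # which makes the ROI invariant under rigid motion of the traces; the
    # chord direction and its support are co-dependent, so iterate briefly
    sv <- tr$surface@vertices
    u <- sv[nrow(sv), ] - sv[1, ]
    u <- u / sqrt(sum(u^2))
    p0 <- sv[1, ]
    for (iter in 1:3) {
        proj <- function(m) (m[, 1] - p0[1]) * u[1] + (m[, 2] - p0[2]) * u[2]
        lo <- max(vapply(tr, function(t) min(proj(t@vertices)), 0))
        hi <- min(vapply(tr, function(t) max(proj(t@vertices)), 0))
        if (hi <= lo) stop("traces share no common support along the chord")
        ss <- proj(sv)
        p0n <- c(approx(ss, sv[, 1], lo, ties = "ordered")$y,
                 approx(ss, sv[, 2], lo, ties = "ordered")$y)
        p1 <- c(approx(ss, sv[, 1], hi, ties = "ordered")$y,
                approx(ss, sv[, 2], hi, ties = "ordered")$y)
        u <- (p1 - p0n) / sqrt(sum((p1 - p0n)^2))
        p0 <- p0n
    }
    step <- median(abs(diff(proj(sv))))
    if (hi - lo < 4 * step)
        stop("common support of the traces is narrower than 4 sampling ",
             "steps")
    w <- sqrt(sum((p1 - p0)^2))
    new("ZonedROI", p0 = p0, p1 = p1, width = w,
        breaks = seq(0, w, length.out = nZones + 1L))
}

#' Per-zone mean thickness between two boundaries
#'
#' Casts `nRays` evenly spaced rays per zone, perpendicular to the ROI chord,
#' and averages the ray-segment lengths between the upper and the lower
#' boundary (linear interpolation between trace vertices). Rays that meet
#' only one boundary are excluded and counted; a zone where more than half
#' the rays are excluded is flagged unmeasurable (`NA`) with a warning.
#'
#' @param profile a [SectionProfile-class]
#' @param upperRole,lowerRole boundary roles, upper above lower in the
#'   anatomical ordering surface > tidemark > cement_line > trab_junction
#' @param roi a [ZonedROI-class] from [defineROI()]
#' @param nRays rays per zone
#' @return data.frame: zone, value (um), nUsed, nExcluded
#' @export
meanThickness <- function(profile, upperRole, lowerRole, roi, nRays = 100L) {
    stopifnot(is(profile, "SectionProfile"), is(roi, "ZonedROI"), nRays >= 1)
    ordUp <- match(upperRole, .ROLES)
    ordLo <- match(lowerRole, .ROLES)
    if (is.na(ordUp) || is.na(ordLo)) stop("unknown boundary role")
    if (ordUp >= ordLo)
        stop(sprintf("'%s' is not above '%s'", upperRole, lowerRole))
    tr <- traces(profile)
    for (r in c(upperRole, lowerRole))
        if (is.null(tr[[r]])) stop("profile is missing trace: ", r)
    up <- .chordFrame(tr[[upperRole]]@vertices, roi@p0, roi@p1)
    lo <- .chordFrame(tr[[lowerRole]]@vertices, roi@p0, roi@p1)
    br <- roi@breaks
    nz <- length(br) - 1L
    out <- data.frame(zone = .ZONES[seq_len(nz)], value = NA_real_,
                      nUsed = 0L, nExcluded = 0L)
    for (z in seq_len(nz)) {
        xs <- br[z] + (seq_len(nRays) - 0.5) / nRays * (br[z + 1] - br[z])
        yu <- .interp(up, xs)
        yl <- .interp(lo, xs)
        len <- yu - yl
        bad <- is.na(len)
        out$nUsed[z] <- sum(!bad)
        out$nExcluded[z] <- sum(bad)
        if (sum(bad) > nRays / 2) {
            warning(sprintf(
                "zone %s: %d of %d rays excluded; flagged unmeasurable",
                .ZONES[z], sum(bad), nRays))
        } else {
            out$value[z] <- mean(len[!bad])
        }
    }
    out
}

#' Total cartilage thickness
#'
#' The exact per-zone sum of the non-calcified and calcified layer
#' thicknesses; missing layers propagate to a missing total.
#'
#' @param nCg,cCg per-zone results from [meanThickness()] (data.frames with
#'   matching `zone`), or plain numeric vectors
#' @return same shape as the inputs with `value` (or the vector) summed
#' @export
totalCartilageThickness <- function(nCg, cCg) {
    if (is.data.frame(nCg) && is.data.frame(cCg)) {
        if (!identical(nCg$zone, cCg$zone))
            stop("zone layouts differ between the two layers")
        out <- nCg
        out$value <- nCg$value + cCg$value
        out$nUsed <- pmin(nCg$nUsed, cCg$nUsed)
        out$nExcluded <- pmax(nCg$nExcluded, cCg$nExcluded)
        return(out)
    }
    if (length(nCg) != length(cCg)) stop("lengths differ")
    nCg + cCg
}

#' Per-zone fibrillation index
#'
#' The arclength L of the articular surface clipped to each zone relative to
#' the zone's straight chord width W: `FI = L / W`. FI is exactly 1 for a
#' straight surface and rises with surface fissuring. The raw excess length
#' `L - W` (um) is also reported.
#'
#' @param profile a [SectionProfile-class] (needs the surface trace)
#' @param roi a [ZonedROI-class]
#' @return data.frame: zone, FI, L (um), W (um), excess (um)
#' @export
fibrillationIndex <- function(profile, roi) {
    stopifnot(is(profile, "SectionProfile"), is(roi, "ZonedROI"))
    tr <- traces(profile)
    if (is.null(tr$surface)) stop("profile is missing trace: surface")
    surf <- .chordFrame(tr$surface@vertices, roi@p0, roi@p1)
    br <- roi@breaks
    nz <- length(br) - 1L
    out <- data.frame(zone = .ZONES[seq_len(nz)], FI = NA_real_,
                      L = NA_real_, W = diff(br), excess = NA_real_)
    for (z in seq_len(nz)) {
        w <- br[z + 1] - br[z]
        if (w <= 0) stop("degenerate zone of zero width")
        if (min(surf[, 1]) > br[z] + 1e-9 ||
            max(surf[, 1]) < br[z + 1] - 1e-9) {
            warning(sprintf("surface trace does not cover zone %s",
                            .ZONES[z]))
            next
        }
        L <- .arclength(.clipPolyline(surf, br[z], br[z + 1]))
        out$L[z] <- L
        out$FI[z] <- L / w
        out$excess[z] <- L - w
    }
    out
}

#' Measure all section parameters of one profile
#'
#' Convenience wrapper running the zoned ROI definition, the three ray-cast
#' layer thicknesses (nCg.Th, cCg.Th, SB.Th), their exact total (Cg.Th) and
#' the fibrillation index, returning one tidy table.
#'
#' @param profile a [SectionProfile-class]
#' @param roi optional precomputed [ZonedROI-class]
#' @param nRays rays per zone for the thickness measurements
#' @return data.frame: specimen, group, joint, compartment, zone, parameter,
#'   value
#' @export
measureSection <- function(profile, roi = NULL, nRays = 100L) {
    if (is.null(roi)) roi <- defineROI(profile)
    ncg <- meanThickness(profile, "surface", "tidemark", roi, nRays)
    ccg <- meanThickness(profile, "tidemark", "cement_line", roi, nRays)
    sb <- meanThickness(profile, "cement_line", "trab_junction", roi, nRays)
    cg <- totalCartilageThickness(ncg, ccg)
    fi <- fibrillationIndex(profile, roi)
    tidy <- function(d, p, col = "value")
        data.frame(specimen = profile@specimen, group = profile@group,
                   joint = profile@joint, compartment = profile@compartment,
                   zone = d$zone, parameter = p, value = d[[col]])
    rbind(tidy(ncg, "nCg.Th"), tidy(ccg, "cCg.Th"), tidy(cg, "Cg.Th"),
          tidy(sb, "SB.Th"), tidy(fi, "FI", "FI"))
}
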