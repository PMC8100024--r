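#' Traced anatomical boundary
#'
#' An ordered planar polyline in micrometres tagged with the anatomical
#' boundary it traces on an undecalcified section: the articular cartilage
#' surface, the tidemark (uncalcified/calcified cartilage junction), the
#' cement line (calcified cartilage/subchondral plate junction) or the
#' plate/trabecular junction.
#'
#' @slot role one of `"surface"`, `"tidemark"`, `"cement_line"`,
#'   `"trab_junction"`
#' @slot vertices two-column numeric matrix (x, y) in micrometres with
#'   strictly increasing x
#' @export
setClass("BoundaryTrace",
    representation(role = "character", vertices = "matrix"))

setValidity("BoundaryTrace", function(object) {
    msg <- character()
    if (length(object@role) != 1 || !object@role %in% .ROLES)
        msg <- c(msg, sprintf("role must be one of %s",
                              paste(.ROLES, collapse = ", ")))
    v <- object@vertices
    if (!is.numeric(v) || ncol(v) != 2)
        msg <- c(msg, "vertices must be a numeric matrix with two columns")
    else {
        if (nrow(v) < 2) msg <- c(msg, "a trace needs at least 2 vertices")
        if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "vertices must be finite")
        else if (any(diff(v[, 1]) <= 0))
            msg <- c(msg, "vertex x coordinates must be strictly increasing")
    }
    if (length(msg)) msg else TRUE
})

#' Section profile of one joint compartment
#'
#' The traced boundaries of one histological section of one femorotibial
#' compartment, plus specimen metadata. A complete profile carries all four
#' boundaries, vertically ordered surface > tidemark > cement line >
#' plate/trabecular junction over their common support.
#'
#' @slot traces named list of [BoundaryTrace-class] objects
#' @slot compartment `"LFC"`, `"MFC"`, `"LTP"` or `"MTP"`
#' @slot specimen,group,joint specimen metadata (group: SHAM/CONT/RIS,
#'   joint: OA/HT)
#' @export
setClass("SectionProfile",
    representation(traces = "list", compartment = "character",
                   specimen = "character", group = "character",
                   joint = "character"))

setValidity("SectionProfile", function(object) {
    msg <- character()
    tr <- object@traces
    roles <- vapply(tr, function(t) t@role, character(1))
    if (is.null(names(tr)) || !identical(unname(roles), unname(names(tr))))
        msg <- c(msg, "traces must be named by their roles")
    if (anyDuplicated(roles))
        msg <- c(msg, "duplicated trace roles")
    if (!all(roles %in% .ROLES))
        msg <- c(msg, "unknown trace role")
    if (length(object@compartment) != 1 ||
        !object@compartment %in% .COMPARTMENTS)
        msg <- c(msg, sprintf("compartment must be one of %s",
                              paste(.COMPARTMENTS, collapse = ", ")))
    # vertical ordering on the common raw-x support, when all four present
    if (!length(msg) && all(.ROLES %in% roles)) {
        lo <- max(vapply(tr, function(t) min(t@vertices[, 1]), 0))
        hi <- min(vapply(tr, function(t) max(t@vertices[, 1]), 0))
        if (hi > lo) {
            xs <- seq(lo, hi, length.out = 64)
            ys <- vapply(.ROLES,
                         function(r) .interp(tr[[r]]@vertices, xs),
                         numeric(64))
            if (any(ys[, 1] < ys[, 2] - 1e-9) ||
                any(ys[, 2] < ys[, 3] - 1e-9) ||
                any(ys[, 3] < ys[, 4] - 1e-9))
                msg <- c(msg, paste("traces must be vertically ordered",
                                    "surface >= tidemark >= cement_line >=",
                                    "trab_junction on the common support"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' Zoned region of interest on a section
#'
#' The straight chord spanning the section's common support, divided into
#' four equal-width zones Z1..Z4. Thickness rays are cast perpendicular to
#' this chord and the fibrillation index is evaluated per zone.
#'
#' @slot p0,p1 chord endpoints (x, y) in micrometres
#' @slot width chord length in micrometres
#' @slot breaks zone boundaries along the chord, `c(0, W/4, W/2, 3W/4, W)`
#' @export
setClass("ZonedROI",
    representation(p0 = "numeric", p1 = "numeric", width = "numeric",
                   breaks = "numeric"))

setValidity("ZonedROI", function(object) {
    msg <- character()
    if (length(object@p0) != 2 || length(object@p1) != 2)
        msg <- c(msg, "p0 and p1 must be length-2 coordinates")
    if (object@width <= 0) msg <- c(msg, "chord width must be > 0")
    b <- object@breaks
    if (length(b) < 2 || b[1] != 0 ||
        abs(b[length(b)] - object@width) > 1e-6 * object@width)
        msg <- c(msg, "breaks must partition [0, width]")
    if (any(diff(b) <= 0)) msg <- c(msg, "breaks must be increasing")
    if (length(msg)) msg else TRUE
})

#' Binary 2D trabecular mask
#'
#' A pre-thresholded binary raster (bone = `TRUE`) with physical pixel size,
#' the unit of 2D trabecular stereology. Stored as an image matrix
#' `[row = y, col = x]`.
#'
#' @slot mask logical matrix, bone = TRUE
#' @slot pixelSize pixel edge in mm
#' @slot site `"femur"` or `"tibia"` (sets the default ROI convention)
#' @export
setClass("TrabMask2D",
    representation(mask = "matrix", pixelSize = "numeric",
                   site = "character"))

setValidity("TrabMask2D", function(object) {
    msg <- character()
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (anyNA(object@mask)) msg <- c(msg, "mask must not contain NA")
    if (length(object@pixelSize) != 1 || object@pixelSize <= 0)
        msg <- c(msg, "pixelSize must be a single positive number (mm)")
    if (!object@site %in% c("femur", "tibia"))
        msg <- c(msg, "site must be 'femur' or 'tibia'")
    if (length(msg)) msg else TRUE
})

#' Binary 3D trabecular volume
#'
#' A binary voxel volume (bone = `TRUE`) with isotropic voxel size and a
#' physical origin, stored as a logical array with dimensions (x, y, z);
#' the centre of voxel (i, j, k) sits at `origin + (c(i,j,k) - 0.5) * voxelSize`.
#'
#' @slot vol logical 3D array, bone = TRUE
#' @slot voxelSize isotropic voxel edge in mm
#' @slot origin physical coordinates (mm) of the volume corner
#' @slot site `"femur"` or `"tibia"`
#' @export
setClass("TrabVolume3D",
    representation(vol = "array", voxelSize = "numeric",
                   origin = "numeric", site = "character"))

setValidity("TrabVolume3D", function(object) {
    msg <- character()
    if (!is.logical(object@vol) || length(dim(object@vol)) != 3)
        msg <- c(msg, "vol must be a logical 3D array")
    if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
        msg <- c(msg, "voxelSize must be a single positive number (mm)")
    if (length(object@origin) != 3)
        msg <- c(msg, "origin must be length-3 (mm)")
    if (!object@site %in% c("femur", "tibia"))
        msg <- c(msg, "site must be 'femur' or 'tibia'")
    if (length(msg)) msg else TRUE
})

#' Cylindrical volume of interest
#'
#' An anatomically placed cylinder (axis along volume z): 2.5 mm diameter
#' with 2.5 mm depth in femoral compartments and 1.5 mm depth in tibial
#' compartments, tagged anterior/central/posterior and medial/lateral.
#'
#' @slot center cylinder centre (x, y, z) in mm
#' @slot diameter cylinder diameter in mm
#' @slot depth cylinder depth along z in mm
#' @slot position `"anterior"`, `"central"` or `"posterior"`
#' @slot side `"medial"` or `"lateral"`
#' @export
setClass("CylVOI",
    representation(center = "numeric", diameter = "numeric",
                   depth = "numeric", position = "character",
                   side = "character"))

setValidity("CylVOI", function(object) {
    msg <- character()
    if (length(object@center) != 3) msg <- c(msg, "center must be length 3")
    if (object@diameter <= 0 || object@depth <= 0)
        msg <- c(msg, "diameter and depth must be > 0")
    if (!object@position %in% c("anterior", "central", "posterior"))
        msg <- c(msg, "position must be anterior/central/posterior")
    if (!object@side %in% c("medial", "lateral"))
        msg <- c(msg, "side must be medial or lateral")
    if (length(msg)) msg else TRUE
})

#' Masked VOI subvolume
#'
#' The result of [extractVOI()]: the bone voxels and the in-cylinder
#' indicator on the VOI's bounding subgrid. Voxels outside the cylinder are
#' excluded from both phases and act as boundary for local-thickness
#' measurements.
#'
#' @slot bone logical array, bone voxels inside the VOI
#' @slot inside logical array, in-cylinder indicator
#' @slot voxelSize voxel edge in mm
#' @slot voi the [CylVOI-class] that produced the region
#' @export
setClass("VoiRegion",
    representation(bone = "array", inside = "array",
                   voxelSize = "numeric", voi = "CylVOI"))

setValidity("VoiRegion", function(object) {
    msg <- character()
    if (!identical(dim(object@bone), dim(object@inside)))
        msg <- c(msg, "bone and inside must have identical dimensions")
    if (length(object@voxelSize) != 1 || object@voxelSize <= 0)
        msg <- c(msg, "voxelSize must be positive")
    if (length(msg)) msg else TRUE
})

#' Run-length profile along an ROI diagonal
#'
#' Ordered bone/marrow run lengths sampled along a diagonal of a rectangular
#' 2D trabecular ROI; run lengths sum exactly to the diagonal length L.
#'
#' @slot runs data.frame with columns `phase` ("bone"/"marrow") and
#'   `length` (mm)
#' @slot L diagonal length in mm
#' @slot which `"main"` or `"anti"`
#' @export
setClass("DiagonalProfile",
    representation(runs = "data.frame", L = "numeric", which = "character"))

setValidity("DiagonalProfile", function(object) {
    msg <- character()
    if (!all(c("phase", "length") %in% names(object@runs)))
        msg <- c(msg, "runs needs columns phase, length")
    else {
        if (!all(object@runs$phase %in% c("bone", "marrow")))
            msg <- c(msg, "phase must be bone or marrow")
        if (abs(sum(object@runs$length) - object@L) > 1e-9 * max(object@L, 1))
            msg <- c(msg, "run lengths must sum to L")
    }
    if (length(msg)) msg else TRUE
})
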