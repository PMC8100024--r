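#' @name accessors
#' @title Accessors for boneMorph data classes
#' @description Small accessor generics: traced boundaries and their roles,
#'   physical pixel/voxel sizes, the binary bone mask, the anatomical site
#'   tag, and the zone layout of a zoned ROI.
#' @param x a boneMorph data object
#' @return the slot value (see each method)
NULL

#' @rdname accessors
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname accessors
#' @export
setGeneric("traceRoles", function(x) standardGeneric("traceRoles"))

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("boneMask", function(x) standardGeneric("boneMask"))

#' @rdname accessors
#' @export
setGeneric("siteTag", function(x) standardGeneric("siteTag"))

#' @rdname accessors
#' @export
setGeneric("zoneBreaks", function(x) standardGeneric("zoneBreaks"))

#' @rdname accessors
#' @export
setGeneric("chordWidth", function(x) standardGeneric("chordWidth"))

#' Bone volume (or area) fraction
#'
#' Percentage of the analysed region occupied by bone: BV/TV for a 3D volume
#' or VOI, Tb.A for a 2D mask.
#'
#' @param x a [TrabVolume3D-class], [VoiRegion-class] or [TrabMask2D-class]
#' @return percentage in `[0, 100]`
#' @export
setGeneric("bvTv", function(x) standardGeneric("bvTv"))

#' Model-independent local thickness
#'
#' Volume-weighted mean maximal-inscribed-sphere thickness of a phase
#' (bone gives Tb.Th, marrow gives Tb.Sp), Hildebrand-Ruegsegger style:
#' squared Euclidean distance transform, distance-ridge extraction, and
#' sphere painting. See the methods vignette for the voxel conventions.
#'
#' @param x a [TrabVolume3D-class] or [VoiRegion-class]
#' @param phase `"bone"` or `"marrow"`
#' @param ... method options (guard margin, see the methods)
#' @return mean thickness in mm with attributes `sd` and `n` (phase voxel
#'   count); `NA` when the phase is empty
#' @export
setGeneric("localThickness",
           function(x, phase = c("bone", "marrow"), ...)
               standardGeneric("localThickness"))
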