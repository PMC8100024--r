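#' @rdname accessors
#' @export
setMethod("traces", "SectionProfile", function(x) x@traces)

#' @rdname accessors
#' @export
setMethod("traceRoles", "SectionProfile", function(x) names(x@traces))

#' @rdname accessors
#' @export
setMethod("pixelSize", "TrabMask2D", function(x) x@pixelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "TrabVolume3D", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "VoiRegion", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setMethod("boneMask", "TrabMask2D", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("boneMask", "TrabVolume3D", function(x) x@vol)

#' @rdname accessors
#' @export
setMethod("siteTag", "TrabMask2D", function(x) x@site)

#' @rdname accessors
#' @export
setMethod("siteTag", "TrabVolume3D", function(x) x@site)

#' @rdname accessors
#' @export
setMethod("zoneBreaks", "ZonedROI", function(x) x@breaks)

#' @rdname accessors
#' @export
setMethod("chordWidth", "ZonedROI", function(x) x@width)

setMethod("show", "BoundaryTrace", function(object) {
    cat(sprintf("BoundaryTrace '%s': %d vertices, x in [%.1f, %.1f] um\n",
                object@role, nrow(object@vertices),
                min(object@vertices[, 1]), max(object@vertices[, 1])))
})

setMethod("show", "SectionProfile", function(object) {
    cat(sprintf("SectionProfile: %s | specimen %s (%s, %s)\n",
                object@compartment, object@specimen, object@group,
                object@joint))
    cat(sprintf("  traces: %s\n", paste(names(object@traces),
                                        collapse = ", ")))
})

setMethod("show", "ZonedROI", function(object) {
    cat(sprintf("ZonedROI: chord width %.1f um, %d zones\n",
                object@width, length(object@breaks) - 1L))
})

setMethod("show", "TrabMask2D", function(object) {
    d <- dim(object@mask)
    cat(sprintf(
        "TrabMask2D (%s): %d x %d px at %.4g mm (%.2f x %.2f mm), Tb.A %.1f%%\n",
        object@site, d[2], d[1], object@pixelSize,
        d[2] * object@pixelSize, d[1] * object@pixelSize,
        100 * mean(object@mask)))
})

setMethod("show", "TrabVolume3D", function(object) {
    d <- dim(object@vol)
    cat(sprintf(
        "TrabVolume3D (%s): %d x %d x %d vox at %.4g mm, BV/TV %.1f%%\n",
        object@site, d[1], d[2], d[3], object@voxelSize,
        100 * mean(object@vol)))
})

setMethod("show", "CylVOI", function(object) {
    cat(sprintf(
        "CylVOI (%s/%s): d %.2f mm x depth %.2f mm at (%.2f, %.2f, %.2f)\n",
        object@side, object@position, object@diameter, object@depth,
        object@center[1], object@center[2], object@center[3]))
})

setMethod("show", "VoiRegion", function(object) {
    nin <- sum(object@inside)
    cat(sprintf("VoiRegion: %d in-VOI voxels at %.4g mm, BV/TV %.1f%%\n",
                nin, object@voxelSize,
                100 * sum(object@bone & object@inside) / max(nin, 1L)))
})

setMethod("show", "DiagonalProfile", function(object) {
    nb <- sum(object@runs$phase == "bone")
    cat(sprintf("DiagonalProfile (%s): L = %.4f mm, %d bone runs\n",
                object@which, object@L, nb))
})
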