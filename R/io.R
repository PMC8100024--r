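#' Read and write section profiles, masks, volumes and cohort tables
#'
#' Section profiles travel as a vertex CSV (`role, index, x_um, y_um`) plus a
#' JSON metadata sidecar; 2D masks as single-channel TIFF or PNG (bone = 1)
#' with pixel size and site in the sidecar; 3D volumes as multi-page TIFF
#' stacks with voxel size and origin in the sidecar; cohort tables as plain
#' CSV.
#'
#' @param profile,mask,volume,cohort the object to write
#' @param path file path; the JSON sidecar replaces the extension with
#'   `.json`
#' @name boneMorph-io
NULL

.sidecarPath <- function(path) sub("\\.[A-Za-z]+$", ".json", path)

#' @rdname boneMorph-io
#' @export
writeSectionProfile <- function(profile, path) {
    stopifnot(is(profile, "SectionProfile"))
    rows <- do.call(rbind, lapply(traces(profile), function(t)
        data.frame(role = t@role, index = seq_len(nrow(t@vertices)),
                   x_um = t@vertices[, 1], y_um = t@vertices[, 2])))
    write.csv(rows, path, row.names = FALSE)
    meta <- list(compartment = profile@compartment,
                 specimen = profile@specimen, group = profile@group,
                 joint = profile@joint)
    jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname boneMorph-io
#' @export
readSectionProfile <- function(path) {
    rows <- read.csv(path, stringsAsFactors = FALSE)
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    tr <- lapply(split(rows, rows$role), function(d) {
        d <- d[order(d$index), ]
        new("BoundaryTrace", role = d$role[1],
            vertices = cbind(d$x_um, d$y_um))
    })
    new("SectionProfile", traces = tr[intersect(.ROLES, names(tr))],
        compartment = meta$compartment, specimen = meta$specimen,
        group = meta$group, joint = meta$joint)
}

#' @rdname boneMorph-io
#' @export
writeTrabMask <- function(mask, path) {
    stopifnot(is(mask, "TrabMask2D"))
    img <- boneMask(mask) * 1
    if (grepl("\\.png$", path, ignore.case = TRUE))
        png::writePNG(img, path)
    else tiff::writeTIFF(img, path)
    jsonlite::write_json(list(pixel_size_mm = pixelSize(mask),
                              site = siteTag(mask)),
                         .sidecarPath(path), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname boneMorph-io
#' @export
readTrabMask <- function(path) {
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    img <- if (grepl("\\.png$", path, ignore.case = TRUE))
        png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    new("TrabMask2D", mask = img > 0.5, pixelSize = meta$pixel_size_mm,
        site = meta$site)
}

#' @rdname boneMorph-io
#' @export
writeTrabVolume <- function(volume, path) {
    stopifnot(is(volume, "TrabVolume3D"))
    pages <- lapply(seq_len(dim(volume@vol)[3]),
                    function(k) t(volume@vol[, , k]) * 1)
    tiff::writeTIFF(pages, path)
    jsonlite::write_json(list(voxel_size_mm = voxelSize(volume),
                              origin_mm = volume@origin,
                              site = siteTag(volume)),
                         .sidecarPath(path), auto_unbox = TRUE)
    invisible(path)
}

#' @rdname boneMorph-io
#' @export
readTrabVolume <- function(path) {
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
        if (length(dim(p)) == 3) p <- p[, , 1]
        t(p) > 0.5
    })
    vol <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    new("TrabVolume3D", vol = vol, voxelSize = meta$voxel_size_mm,
        origin = as.numeric(meta$origin_mm), site = meta$site)
}

#' @rdname boneMorph-io
#' @export
writeCohort <- function(cohort, path) {
    write.csv(cohort, path, row.names = FALSE)
    invisible(path)
}

#' @rdname boneMorph-io
#' @export
readCohort <- function(path) {
    d <- read.csv(path, stringsAsFactors = FALSE)
    d$zone <- as.character(d$zone)
    d
}
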