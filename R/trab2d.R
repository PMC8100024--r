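#' Place the rectangular trabecular ROI on a 2D image
#'
#' Crops the standard subchondral trabecular ROI - 2.5 x 1.5 mm for femoral
#' and 1.5 x 1.5 mm for tibial sections - centred on the image midpoint, or
#' on an explicit centre.
#'
#' @param image a [TrabMask2D-class] holding the full binary section image
#' @param site `"femur"` or `"tibia"`; defaults to the image's tag
#' @param center optional ROI centre `c(x, y)` in mm
#' @param roiSize optional override `c(width, height)` in mm
#' @return a [TrabMask2D-class] cropped to the ROI
#' @export
placeROI <- function(image, site = siteTag(image), center = NULL,
                     roiSize = NULL) {
    stopifnot(is(image, "TrabMask2D"), site %in% c("femur", "tibia"))
    if (is.null(roiSize)) roiSize <- .ROI_2D[[site]]
    h <- pixelSize(image)
    d <- dim(boneMask(image))
    npx <- round(roiSize[1] / h)
    npy <- round(roiSize[2] / h)
    if (npx > d[2] || npy > d[1])
        stop(sprintf("ROI %.2f x %.2f mm exceeds image %.2f x %.2f mm",
                     roiSize[1], roiSize[2], d[2] * h, d[1] * h))
    if (is.null(center)) center <- c(d[2], d[1]) * h / 2
    j0 <- round(center[1] / h - npx / 2)
    i0 <- round(center[2] / h - npy / 2)
    if (j0 < 0 || i0 < 0 || j0 + npx > d[2] || i0 + npy > d[1])
        stop("ROI exceeds image bounds at the requested centre")
    new("TrabMask2D",
        mask = boneMask(image)[(i0 + 1):(i0 + npy), (j0 + 1):(j0 + npx),
                               drop = FALSE],
        pixelSize = h, site = site)
}

#' Trabecular area fraction (Tb.A)
#'
#' Percentage of ROI pixels that are bone.
#'
#' @param mask a [TrabMask2D-class]
#' @return Tb.A in percent
#' @export
tbArea <- function(mask) {
    stopifnot(is(mask, "TrabMask2D"))
    m <- boneMask(mask)
    if (length(m) == 0) stop("empty ROI")
    v <- 100 * mean(m)
    if (v == 0) warning("ROI contains no bone")
    v
}

# sample one diagonal into phase runs
.oneDiagonal <- function(m, h, which) {
    d <- dim(m)
    Wmm <- d[2] * h
    Hmm <- d[1] * h
    L <- sqrt(Wmm^2 + Hmm^2)
    n <- max(2L, ceiling(L / (h / 2)))
    tmid <- (seq_len(n) - 0.5) / n
    if (which == "main") {
        xs <- tmid * Wmm
        ys <- tmid * Hmm
    } else {
        xs <- (1 - tmid) * Wmm
        ys <- tmid * Hmm
    }
    j <- pmin(pmax(ceiling(xs / h), 1L), d[2])
    i <- pmin(pmax(ceiling(ys / h), 1L), d[1])
    bone <- m[cbind(i, j)]
    r <- rle(bone)
    runs <- data.frame(phase = ifelse(r$values, "bone", "marrow"),
                       length = r$lengths * (L / n))
    new("DiagonalProfile", runs = runs, L = L, which = which)
}

#' Run-length profile along the ROI diagonal
#'
#' Samples the binary mask along the chosen ROI diagonal at half-pixel steps
#' and merges consecutive samples into bone/marrow runs. Run lengths sum
#' exactly to the diagonal length `L = sqrt(width^2 + height^2)`.
#'
#' @param mask a [TrabMask2D-class] (already cropped to the ROI)
#' @param which `"main"` (top-left to bottom-right), `"anti"`, or `"both"`
#' @return a [DiagonalProfile-class], or a list of two for `"both"`
#' @export
diagonalProfile <- function(mask, which = c("main", "anti", "both")) {
    stopifnot(is(mask, "TrabMask2D"))
    which <- match.arg(which)
    m <- boneMask(mask)
    h <- pixelSize(mask)
    if (which == "both")
        list(main = .oneDiagonal(m, h, "main"),
             anti = .oneDiagonal(m, h, "anti"))
    else .oneDiagonal(m, h, which)
}

#' Diagonal-intercept trabecular metrics
#'
#' From the run-length profile: `Tb.N` is the count of bone runs crossed by
#' the diagonal, `Tb.Th` the mean bone-run (intercept) length, and `Tb.Sp`
#' follows the intercept identity `Tb.Sp = (L / Tb.N) - Tb.Th`, which holds
#' exactly by construction. Runs clipped by the ROI corners count, so sparse
#' masks are not biased low in Tb.N. With two diagonals the metrics are
#' averaged.
#'
#' Note the diagonal crosses trabeculae obliquely, so intercept `Tb.Th` is
#' biased high relative to the true (model-independent 3D) thickness; the
#' bias is the secant obliquity factor and disappears only when the diagonal
#' runs along the trabecular normal.
#'
#' @param profile a [DiagonalProfile-class] or a list of them (from
#'   `which = "both"`)
#' @return data.frame: Tb.N (count), Tb.Th (mm), Tb.Sp (mm), L (mm)
#' @export
trab2DMetrics <- function(profile) {
    one <- function(p) {
        stopifnot(is(p, "DiagonalProfile"))
        b <- p@runs$length[p@runs$phase == "bone"]
        if (length(b) == 0) {
            warning("no bone runs along the diagonal; metrics are missing")
            return(data.frame(Tb.N = NA_real_, Tb.Th = NA_real_,
                              Tb.Sp = NA_real_, L = p@L))
        }
        tbn <- length(b)
        tbth <- mean(b)
        data.frame(Tb.N = tbn, Tb.Th = tbth, Tb.Sp = p@L / tbn - tbth,
                   L = p@L)
    }
    if (is(profile, "DiagonalProfile")) return(one(profile))
    res <- do.call(rbind, lapply(profile, one))
    as.data.frame(lapply(res, mean))
}

#' Measure all 2D trabecular parameters of a mask
#'
#' @param mask a [TrabMask2D-class] cropped to the ROI
#' @param diagonal passed to [diagonalProfile()]
#' @return one-row data.frame: Tb.A (%), Tb.N, Tb.Th (mm), Tb.Sp (mm)
#' @export
measureTrabMask <- function(mask, diagonal = "main") {
    met <- trab2DMetrics(diagonalProfile(mask, diagonal))
    cbind(data.frame(Tb.A = tbArea(mask)),
          met[, c("Tb.N", "Tb.Th", "Tb.Sp")])
}
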