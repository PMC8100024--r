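# internal constants and helpers

.GROUPS <- c("SHAM", "CONT", "RIS")
.JOINTS <- c("OA", "HT")
.COMPARTMENTS <- c("LFC", "MFC", "LTP", "MTP")
.ZONES <- c("Z1", "Z2", "Z3", "Z4")
.ROLES <- c("surface", "tidemark", "cement_line", "trab_junction")

# default rectangular 2D trabecular ROI, width x height in mm
.ROI_2D <- list(femur = c(2.5, 1.5), tibia = c(1.5, 1.5))
# default cylindrical VOI depth in mm (diameter is 2.5 mm for both sites)
.VOI_DEPTH <- c(femur = 2.5, tibia = 1.5)
.VOI_DIAMETER <- 2.5

#' Draw from a normal distribution truncated at zero
#'
#' Inverse-CDF sampling from N(mean, sd) conditioned on positive values, used
#' by the cohort generator so that physically positive quantities never go
#' negative even in high-CV cells. `sd = 0` returns the mean exactly.
#'
#' @param n number of draws
#' @param mean,sd parameters of the untruncated normal
#' @return numeric vector of length `n`, all values > 0 (or == mean if sd 0)
#' @keywords internal
rtruncnorm0 <- function(n, mean, sd) {
    if (any(sd < 0)) stop("sd must be >= 0")
    mean <- rep_len(mean, n)
    sd <- rep_len(sd, n)
    lo <- pnorm(0, mean = mean, sd = sd)
    lo[sd == 0] <- 0
    u <- lo + runif(n) * (1 - lo)
    out <- qnorm(u, mean = mean, sd = sd)
    out[sd == 0] <- mean[sd == 0]
    out
}

# linear interpolation of a polyline given as (x, y) with strictly increasing
# x; returns NA outside the support
.interp <- function(xy, xout) {
    approx(xy[, 1], xy[, 2], xout = xout, method = "linear",
           rule = 1, ties = "ordered")$y
}

# rotate/translate 2D points into the frame of the chord p0 -> p1:
# new x along the chord, new y perpendicular (left of travel)
.chordFrame <- function(xy, p0, p1) {
    u <- p1 - p0
    w <- sqrt(sum(u^2))
    u <- u / w
    nrm <- c(-u[2], u[1])
    dx <- xy[, 1] - p0[1]
    dy <- xy[, 2] - p0[2]
    cbind(dx * u[1] + dy * u[2], dx * nrm[1] + dy * nrm[2])
}

# exact arclength of a polyline
.arclength <- function(xy) {
    if (nrow(xy) < 2) return(0)
    sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}

# clip a function-graph polyline (x strictly increasing) to [x0, x1],
# interpolating the endpoints
.clipPolyline <- function(xy, x0, x1) {
    x <- xy[, 1]
    keep <- x > x0 & x < x1
    xs <- c(x0, x[keep], x1)
    ys <- c(.interp(xy, x0), xy[keep, 2], .interp(xy, x1))
    ok <- !is.na(ys)
    cbind(xs[ok], ys[ok])
}

# exact mean of the piecewise-linear difference upper(x) - lower(x) over
# [x0, x1] (trapezoid over the union of knots, which is exact for piecewise
# linear integrands); the interval is shrunk by at most floating-point slack
# to the joint coverage of the two polylines
.meanGap <- function(upper, lower, x0, x1) {
    cov0 <- max(x0, upper[1, 1], lower[1, 1])
    cov1 <- min(x1, upper[nrow(upper), 1], lower[nrow(lower), 1])
    if (cov1 <= cov0) return(NA_real_)
    knots <- sort(unique(c(cov0, cov1,
                           upper[upper[, 1] > cov0 & upper[, 1] < cov1, 1],
                           lower[lower[, 1] > cov0 & lower[, 1] < cov1, 1])))
    g <- .interp(upper, knots) - .interp(lower, knots)
    if (anyNA(g)) return(NA_real_)
    sum(diff(knots) * (g[-1] + g[-length(g)]) / 2) / (cov1 - cov0)
}

# deterministic derived seeds (kept below 2^31)
.deriveSeed <- function(seed, offset) {
    (as.integer(seed) + as.integer(offset) * 1009L) %% 2147483587L
}
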