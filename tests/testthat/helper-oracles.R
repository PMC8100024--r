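# shared fixture builders and independent oracles

# flat boundary trace at height y over [x0, x1]
flatTrace <- function(role, y, x0 = 0, x1 = 8000, step = 10) {
    x <- seq(x0, x1, by = step)
    new("BoundaryTrace", role = role, vertices = cbind(x, y))
}

# a simple four-boundary profile with flat layers
flatProfile <- function(nCg = 300, cCg = 120, SB = 350, x0 = 0, x1 = 8000,
                        step = 10, compartment = "MTP") {
    y0 <- 0
    new("SectionProfile",
        traces = list(
            surface = flatTrace("surface", y0 + SB + cCg + nCg, x0, x1, step),
            tidemark = flatTrace("tidemark", y0 + SB + cCg, x0, x1, step),
            cement_line = flatTrace("cement_line", y0 + SB, x0, x1, step),
            trab_junction = flatTrace("trab_junction", y0, x0, x1, step)),
        compartment = compartment, specimen = "FIX-1", group = "CONT",
        joint = "OA")
}

# profile whose surface has one semicircular notch (radius r, centred at cx)
# in an otherwise straight surface; exact arclength of the notched span is
# (x1 - x0) - 2 r + pi r
notchedProfile <- function(r = 100, cx = 500, x0 = 0, x1 = 1000,
                           surfY = 800) {
    xs <- seq(x0, cx - r, by = 1)
    phi <- seq(0, pi, length.out = 721)[-1]
    notch <- cbind(cx - r * cos(phi), surfY - r * sin(phi))
    notch[nrow(notch), 2] <- surfY
    xe <- seq(cx + r + 1, x1, by = 1)
    v <- rbind(cbind(xs, surfY), notch[-nrow(notch), ], cbind(cx + r, surfY),
               cbind(xe, surfY))
    v <- v[order(v[, 1]), ]
    v <- v[c(TRUE, diff(v[, 1]) > 0), ]
    tr <- list(
        surface = new("BoundaryTrace", role = "surface", vertices = v),
        tidemark = flatTrace("tidemark", 400, x0, x1, 5),
        cement_line = flatTrace("cement_line", 300, x0, x1, 5),
        trab_junction = flatTrace("trab_junction", 0, x0, x1, 5))
    new("SectionProfile", traces = tr, compartment = "MTP",
        specimen = "FIX-NOTCH", group = "CONT", joint = "OA")
}

# quadrature oracle for the arclength/chord ratio of a sinusoidal surface
sinusoidFIOracle <- function(amplitude, wavelength, x0, x1) {
    f <- function(x)
        sqrt(1 + (amplitude * 2 * pi / wavelength *
                  cos(2 * pi * x / wavelength))^2)
    stats::integrate(f, x0, x1, rel.tol = 1e-10)$value / (x1 - x0)
}

# rigid rotation + translation of every trace of a profile
transformProfile <- function(profile, angleDeg, shift = c(0, 0)) {
    th <- angleDeg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    tr <- lapply(traces(profile), function(t) {
        v <- t@vertices %*% t(R)
        v[, 1] <- v[, 1] + shift[1]
        v[, 2] <- v[, 2] + shift[2]
        new("BoundaryTrace", role = t@role, vertices = v)
    })
    new("SectionProfile", traces = tr, compartment = profile@compartment,
        specimen = profile@specimen, group = profile@group,
        joint = profile@joint)
}

# exact two-sided Mann-Whitney p for complete enumeration of group labels
mwExactOracle <- function(a, b) {
    pooled <- c(a, b)
    n1 <- length(a)
    idx <- utils::combn(length(pooled), n1)
    uObs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
    uAll <- apply(idx, 2, function(ii)
        sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2)
    m <- length(a) * length(b)
    dev <- abs(uAll - m / 2)
    mean(dev >= abs(uObs - m / 2) - 1e-12)
}
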