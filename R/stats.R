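#' Gate between parametric and nonparametric testing
#'
#' Normality is assessed per group with the Shapiro-Wilk test and variance
#' homogeneity with Levene's test (classical mean-centred form). The
#' comparison is run parametrically only when every group passes
#' Shapiro-Wilk at `alpha` and Levene passes at `alpha`; groups smaller than
#' three observations, or degenerate (constant) groups, force the
#' nonparametric route with a warning.
#'
#' @param values numeric measurements
#' @param groups grouping factor aligned with `values`
#' @param alpha gate level
#' @return list with `family` ("parametric"/"nonparametric"), `shapiro`
#'   (named per-group p), `levene` (p), `reason`
#' @export
gateTests <- function(values, groups, alpha = 0.05) {
    groups <- factor(groups)
    sp <- split(values, groups)
    ns <- lengths(sp)
    if (any(ns < 3)) {
        warning("group(s) with n < 3; forcing nonparametric tests")
        return(list(family = "nonparametric",
                    shapiro = setNames(rep(NA_real_, length(sp)), names(sp)),
                    levene = NA_real_, reason = "n < 3"))
    }
    shap <- vapply(sp, function(v) {
        if (length(unique(v)) == 1) return(NA_real_)
        shapiro.test(v)$p.value
    }, numeric(1))
    if (anyNA(shap)) {
        warning("degenerate (constant) group; forcing nonparametric tests")
        return(list(family = "nonparametric", shapiro = shap,
                    levene = NA_real_, reason = "degenerate variance"))
    }
    lev <- car::leveneTest(values ~ groups, center = mean)[1, "Pr(>F)"]
    ok <- all(shap > alpha) && lev > alpha
    list(family = if (ok) "parametric" else "nonparametric",
         shapiro = shap, levene = lev,
         reason = if (ok) "all gates passed"
                  else if (any(shap <= alpha)) "Shapiro-Wilk failed"
                  else "Levene failed")
}

#' Two-group comparison
#'
#' Student's t-test (pooled variance) for the parametric route, two-tailed
#' Mann-Whitney U for the nonparametric one (exact p for small samples
#' without ties, normal approximation with continuity/tie correction
#' otherwise). `family = "auto"` routes through [gateTests()]. Unpaired by
#' default; `paired = TRUE` uses the paired t / Wilcoxon signed-rank.
#'
#' @param a,b numeric samples
#' @param family `"auto"`, `"parametric"` or `"nonparametric"`
#' @param paired compare within-specimen pairs
#' @param alpha gate level for `"auto"`
#' @return one-row data.frame: test, statistic, p, family, n1, n2,
#'   shapiroMin, levene
#' @export
compareTwo <- function(a, b, family = c("auto", "parametric",
                                        "nonparametric"),
                       paired = FALSE, alpha = 0.05) {
    family <- match.arg(family)
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (!length(a) || !length(b)) stop("empty sample")
    shapMin <- NA_real_
    lev <- NA_real_
    if (family == "auto") {
        g <- gateTests(c(a, b), rep(c("a", "b"), c(length(a), length(b))),
                       alpha)
        family <- g$family
        shapMin <- suppressWarnings(min(g$shapiro))
        lev <- g$levene
    }
    if (family == "parametric") {
        tt <- t.test(a, b, var.equal = TRUE, paired = paired)
        out <- data.frame(test = if (paired) "paired t" else "Student t",
                          statistic = unname(tt$statistic), p = tt$p.value)
    } else {
        wt <- suppressWarnings(wilcox.test(a, b, paired = paired))
        out <- data.frame(test = if (paired) "Wilcoxon signed-rank"
                                 else "Mann-Whitney U",
                          statistic = unname(wt$statistic), p = wt$p.value)
    }
    out$family <- family
    out$n1 <- length(a)
    out$n2 <- length(b)
    out$shapiroMin <- shapMin
    out$levene <- lev
    out
}

#' Holm-Sidak step-down adjustment
#'
#' Sorted ascending, the i-th smallest of m p-values is adjusted to
#' `1 - (1 - p_(i))^(m - i + 1)`, with monotonicity enforced by running
#' maxima. Adjusted values are never below the raw ones.
#'
#' @param p raw p-values
#' @return adjusted p-values in the original order
#' @export
holmSidak <- function(p) {
    m <- length(p)
    if (m == 0) return(numeric(0))
    o <- order(p)
    adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
    adj <- pmin(cummax(adj), 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z statistics on mean ranks with tie correction,
#' `z = (Ri - Rj) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/ni + 1/nj))` with
#' `T = sum(t^3 - t)` over tie groups, two-sided normal p, adjusted by the
#' same Holm-style step-down as the parametric post-hoc.
#'
#' @param values numeric measurements
#' @param groups grouping factor
#' @return data.frame: group1, group2, z, p, pAdjusted
#' @export
dunnTest <- function(values, groups) {
    groups <- factor(groups)
    N <- length(values)
    r <- rank(values)
    tieTab <- table(values)
    Tcorr <- sum(tieTab^3 - tieTab)
    sig2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
    mr <- tapply(r, groups, mean)
    ns <- tapply(r, groups, length)
    gl <- levels(groups)
    pairs <- utils::combn(gl, 2)
    z <- apply(pairs, 2, function(pr) {
        (mr[[pr[1]]] - mr[[pr[2]]]) /
            sqrt(sig2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    })
    p <- 2 * pnorm(-abs(z))
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
               pAdjusted = holmSidak(p))
}

#' Multi-group comparison with post-hoc contrasts
#'
#' One-way ANOVA with Holm-Sidak-adjusted pairwise pooled-variance t
#' contrasts for the parametric route; Kruskal-Wallis with Dunn's post-hoc
#' (Holm-style step-down) for the nonparametric one. With fewer than three
#' groups the comparison defers to [compareTwo()].
#'
#' @param values numeric measurements
#' @param groups grouping factor
#' @param family `"auto"`, `"parametric"` or `"nonparametric"`
#' @param alpha gate level for `"auto"`
#' @return list with `omnibus` (one-row data.frame: test, statistic, p,
#'   family) and `contrasts` (data.frame: group1, group2, statistic, p,
#'   pAdjusted)
#' @export
compareK <- function(values, groups, family = c("auto", "parametric",
                                                "nonparametric"),
                     alpha = 0.05) {
    family <- match.arg(family)
    ok <- !is.na(values)
    values <- values[ok]
    groups <- factor(groups[ok])
    if (nlevels(groups) < 3) {
        sp <- split(values, groups)
        res <- compareTwo(sp[[1]], sp[[2]], family, alpha = alpha)
        return(list(omnibus = res[, c("test", "statistic", "p", "family")],
                    contrasts = data.frame(
                        group1 = names(sp)[1], group2 = names(sp)[2],
                        statistic = res$statistic, p = res$p,
                        pAdjusted = res$p)))
    }
    if (family == "auto") family <- gateTests(values, groups, alpha)$family
    if (family == "parametric") {
        fit <- aov(values ~ groups)
        sm <- summary(fit)[[1]]
        omni <- data.frame(test = "one-way ANOVA",
                           statistic = sm[1, "F value"],
                           p = sm[1, "Pr(>F)"], family = family)
        # pairwise pooled-sd t contrasts, Holm-Sidak step-down
        msw <- sm[2, "Mean Sq"]
        dfw <- sm[2, "Df"]
        sp <- split(values, groups)
        prs <- utils::combn(names(sp), 2)
        tstat <- apply(prs, 2, function(pr) {
            (mean(sp[[pr[1]]]) - mean(sp[[pr[2]]])) /
                sqrt(msw * (1 / length(sp[[pr[1]]]) + 1 / length(sp[[pr[2]]])))
        })
        praw <- 2 * pt(-abs(tstat), dfw)
        contr <- data.frame(group1 = prs[1, ], group2 = prs[2, ],
                            statistic = tstat, p = praw,
                            pAdjusted = holmSidak(praw))
    } else {
        kw <- kruskal.test(values, groups)
        omni <- data.frame(test = "Kruskal-Wallis",
                           statistic = unname(kw$statistic),
                           p = kw$p.value, family = family)
        dn <- dunnTest(values, groups)
        contr <- data.frame(group1 = dn$group1, group2 = dn$group2,
                            statistic = dn$z, p = dn$p,
                            pAdjusted = dn$pAdjusted)
    }
    list(omnibus = omni, contrasts = contr)
}

#' 2D-3D correlation table
#'
#' Specimen-matched Pearson correlations between 2D histomorphometric and 3D
#' micro-CT trabecular parameters (Tb.A vs BV/TV, Tb.Th, Tb.Sp, Tb.N), with
#' per-method means and SDs, one row per parameter pair.
#'
#' @param paired data.frame with columns `specimen`, `parameter`, `value2d`,
#'   `value3d`
#' @return data.frame: parameter, n, mean2d, sd2d, mean3d, sd3d, r, p
#' @export
correlate2D3D <- function(paired) {
    stopifnot(all(c("specimen", "parameter", "value2d", "value3d") %in%
                  names(paired)))
    out <- lapply(split(paired, paired$parameter), function(d) {
        cc <- complete.cases(d$value2d, d$value3d)
        d <- d[cc, ]
        n <- nrow(d)
        row <- data.frame(parameter = d$parameter[1], n = n,
                          mean2d = mean(d$value2d), sd2d = sd(d$value2d),
                          mean3d = mean(d$value3d), sd3d = sd(d$value3d),
                          r = NA_real_, p = NA_real_)
        if (n < 3) {
            warning("fewer than 3 complete pairs for ", row$parameter)
            return(row)
        }
        if (sd(d$value2d) == 0 || sd(d$value3d) == 0) {
            warning("zero variance for ", row$parameter,
                    "; correlation is missing")
            return(row)
        }
        ct <- cor.test(d$value2d, d$value3d, method = "pearson")
        row$r <- unname(ct$estimate)
        row$p <- ct$p.value
        row
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
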