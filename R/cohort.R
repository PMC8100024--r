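#' Default cohort parameterization
#'
#' The built-in cell-level (mean, sd) parameterization of the synthetic
#' cohort generator. It encodes the group-level summary statistics of a
#' three-arm rabbit ACLT knee-OA study design - sham surgery (SHAM), placebo
#' control (CONT) and risedronate-treated (RIS) animals, each with a
#' surgically destabilised (OA) and a contralateral healthy (HT) joint,
#' measured per compartment (LFC/MFC/LTP/MTP) and, for section parameters,
#' per zone (Z1-Z4): layer thicknesses (nCg.Th, cCg.Th, Cg.Th, SB.Th, um),
#' fibrillation index (FI) and 2D trabecular indices (Tb.A %, Tb.Th mm,
#' Tb.Sp mm, Tb.N).
#'
#' @return data.frame with columns joint, group, zone (NA for trabecular
#'   parameters), compartment, parameter, mean, sd
#' @export
cohortDefaults <- function() {
    files <- c("default_thickness_params.csv",
               "default_fibrillation_params.csv",
               "default_trabecular2d_params.csv")
    tabs <- lapply(files, function(f) {
        p <- system.file("extdata", f, package = "boneMorph", mustWork = TRUE)
        read.csv(p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    out$zone <- as.character(out$zone)
    out
}

#' Cohort specification
#'
#' Study design of a synthetic cohort: group sizes (default eight animals per
#' group, with the SHAM group reducible to seven to mirror a single animal
#' loss), the compartments, zones and parameters to simulate, the cell-level
#' (mean, sd) parameterization, and an optional exchangeable between-zone
#' correlation.
#'
#' @param nPerGroup named integer vector of animals per group, or a single
#'   integer applied to all of SHAM, CONT, RIS
#' @param compartments,zones,parameters subsets of the design to simulate
#' @param params cell parameterization as returned by [cohortDefaults()]
#' @param betweenZoneCorrelation exchangeable correlation (on the latent
#'   normal scale) between the zones of one specimen x compartment x
#'   parameter; 0 draws every record independently
#' @param seed integer seed
#' @return a validated spec (list) for [genCohort()]
#' @export
cohortSpec <- function(nPerGroup = 8L,
                       compartments = .COMPARTMENTS,
                       zones = .ZONES,
                       parameters = NULL,
                       params = cohortDefaults(),
                       betweenZoneCorrelation = 0,
                       seed = 1L) {
    if (length(nPerGroup) == 1L && is.null(names(nPerGroup)))
        nPerGroup <- setNames(rep(as.integer(nPerGroup), 3L), .GROUPS)
    if (!all(.GROUPS %in% names(nPerGroup)))
        stop("nPerGroup must name SHAM, CONT and RIS")
    nPerGroup <- vapply(nPerGroup[.GROUPS], as.integer, integer(1))
    stopifnot(all(nPerGroup >= 1L), all(params$sd >= 0),
              betweenZoneCorrelation >= 0, betweenZoneCorrelation < 1)
    if (is.null(parameters)) parameters <- unique(params$parameter)
    stopifnot(all(compartments %in% .COMPARTMENTS),
              all(zones %in% .ZONES))
    structure(list(nPerGroup = nPerGroup, compartments = compartments,
                   zones = zones, parameters = parameters, params = params,
                   betweenZoneCorrelation = betweenZoneCorrelation,
                   seed = as.integer(seed)),
              class = "CohortSpec")
}

#' Simulate a measurement cohort
#'
#' Draws every requested cell record from a normal distribution truncated at
#' zero with the configured cell (mean, sd), independently across cells by
#' default (an exchangeable between-zone correlation can be configured on the
#' latent scale). Output is the long-format table the statistics stage
#' consumes.
#'
#' @param spec a [cohortSpec()]
#' @return data.frame with columns specimen, group, joint, compartment, zone
#'   (NA for per-ROI trabecular parameters), parameter, value
#' @export
genCohort <- function(spec) {
    stopifnot(inherits(spec, "CohortSpec"))
    pt <- spec$params
    keep <- pt$compartment %in% spec$compartments &
        pt$parameter %in% spec$parameters &
        (is.na(pt$zone) | pt$zone %in% spec$zones)
    pt <- pt[keep, , drop = FALSE]
    # every requested cell must be parameterized
    want <- expand.grid(joint = .JOINTS, group = .GROUPS,
                        compartment = spec$compartments,
                        parameter = spec$parameters,
                        stringsAsFactors = FALSE)
    have <- unique(pt[, c("joint", "group", "compartment", "parameter")])
    key <- function(d) paste(d$joint, d$group, d$compartment, d$parameter)
    missing <- setdiff(key(want), key(have))
    if (length(missing))
        stop("no (mean, sd) parameterization for cell(s): ",
             paste(utils::head(missing, 5), collapse = "; "))
    rho <- spec$betweenZoneCorrelation
    withr::with_seed(spec$seed, {
        recs <- lapply(.GROUPS, function(g) {
            n <- spec$nPerGroup[[g]]
            sub <- pt[pt$group == g, , drop = FALSE]
            # one latent shared normal per specimen x joint x compartment x
            # parameter induces the between-zone correlation
            reps <- sub[rep(seq_len(nrow(sub)), each = n), , drop = FALSE]
            reps$specimen <- paste0(g, "-", rep(seq_len(n), times = nrow(sub)))
            if (rho > 0) {
                shareKey <- paste(reps$specimen, reps$joint,
                                  reps$compartment, reps$parameter)
                uk <- unique(shareKey)
                zshare <- setNames(rnorm(length(uk)), uk)
                z <- sqrt(rho) * zshare[shareKey] +
                    sqrt(1 - rho) * rnorm(nrow(reps))
                # map latent z through the truncated-normal inverse CDF
                lo <- pnorm(0, reps$mean, reps$sd)
                lo[reps$sd == 0] <- 0
                u <- lo + pnorm(z) * (1 - lo)
                reps$value <- ifelse(reps$sd == 0, reps$mean,
                                     qnorm(u, reps$mean, reps$sd))
            } else {
                reps$value <- rtruncnorm0(nrow(reps), reps$mean, reps$sd)
            }
            reps
        })
        recs <- do.call(rbind, recs)
        rownames(recs) <- NULL
        recs[, c("specimen", "group", "joint", "compartment", "zone",
                 "parameter", "value")]
    })
}
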