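#' @include enrichment.R
NULL

#' Steady-state degradation rate constant
#'
#' Under a constant pool (synthesis balancing degradation), the fraction of
#' protein remaining unlabelled decays as \eqn{1 - f = e^{-k_{deg} t}}, so
#' \deqn{k_{deg} = -\ln(1 - f) / t.}
#'
#' @param f fraction-new in [0, 1).
#' @param t labelling time, days (> 0).
#' @return kdeg, 1/day.
#' @examples
#' kdegSteady(1 - exp(-1), 1)  # 1/day
#' @export
kdegSteady <- function(f, t) {
    if (!is.finite(t) || t <= 0) stop("'t' must be > 0 days")
    if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
        stop("'f' must be in [0, 1); f = 1 implies an infinite rate")
    -log(1 - f) / t
}

#' Non-steady-state degradation rate constant
#'
#' When the pool size changes during labelling (atrophy), the fraction of
#' original protein remaining is \eqn{P_0 e^{-k_{deg} t} / P(t) = 1 - f},
#' and with the pool ratio \eqn{r = P(t)/P_0} this inverts to
#' \deqn{k_{deg} = -\ln\big(r (1 - f)\big) / t.}
#' At r = 1 this reduces analytically to [kdegSteady()]. The inversion is
#' verified against numerical integration of dP/dt = ksyn - kdeg P in the
#' test suite.
#'
#' When \eqn{r (1 - f) > 1} the observation implies a negative degradation
#' rate; no estimate is emitted — the sample is returned as NA with an
#' \code{invalid} attribute and logged.
#'
#' @param f fraction-new in [0, 1) (vectorised).
#' @param r pool ratio P(t)/P0 (> 0), e.g. a CoxIV densitometry ratio for
#'   the mitochondrial fraction or a muscle-mass ratio for myofibrillar.
#' @param t labelling time, days.
#' @return kdeg, 1/day (NA where flagged invalid), with attribute
#'   \code{invalid} giving the flagged count.
#' @examples
#' kdegNonsteady(f = 0.2, r = 0.9, t = 5)
#' @export
kdegNonsteady <- function(f, r, t) {
    if (!is.finite(t) || t <= 0) stop("'t' must be > 0 days")
    n <- max(length(f), length(r))
    f <- rep_len(f, n); r <- rep_len(r, n)
    if (any(!is.finite(r)) || any(r <= 0)) stop("'r' must be > 0")
    if (any(!is.finite(f)) || any(f < 0) || any(f >= 1))
        stop("'f' must be in [0, 1)")
    arg <- r * (1 - f)
    invalid <- arg > 1
    kd <- ifelse(invalid, NA_real_, -log(arg) / t)
    if (any(invalid)) {
        .logEvent("kdeg_invalid", sum(invalid))
        warning(sprintf("%d sample(s) with r*(1-f) > 1 imply negative degradation; flagged invalid",
                        sum(invalid)))
    }
    structure(kd, invalid = sum(invalid))
}

#' Non-steady-state synthesis rate
#'
#' Given the degradation constant, the observed fraction-new and pool
#' ratio fix the equilibrium pool via
#' \eqn{P(t) = P_{eq} + (P_0 - P_{eq}) e^{-k_{deg} t}} with
#' \eqn{e^{-k_{deg} t} = r (1 - f)}, so
#' \deqn{k_{syn} = k_{deg} P_{eq} = k_{deg} \frac{P_0\, r f}{1 - r(1 - f)}.}
#' At r = 1 this is the steady-state relation \eqn{k_{syn} = k_{deg} P_0}
#' (equilibrium pool = current pool). The kdeg = 0 limit (pool growing
#' linearly) gives \eqn{k_{syn} = f r P_0 / t}.
#'
#' @param kdeg degradation constant from [kdegNonsteady()] (1/day).
#' @param f fraction-new.
#' @param r pool ratio.
#' @param P0 initial pool size (default 1: rates in initial-pool fractions
#'   per day).
#' @param t labelling time, days.
#' @return ksyn, pool units/day (NA where kdeg is NA).
#' @examples
#' kd <- kdegNonsteady(0.2, 0.9, 5)
#' ksynNonsteady(kd, 0.2, 0.9, 1, 5)
#' @export
ksynNonsteady <- function(kdeg, f, r, P0 = 1, t) {
    if (!is.finite(t) || t <= 0) stop("'t' must be > 0 days")
    if (any(P0 <= 0)) stop("'P0' must be > 0")
    n <- max(length(kdeg), length(f), length(r), length(P0))
    kdeg <- rep_len(as.numeric(kdeg), n); f <- rep_len(f, n)
    r <- rep_len(r, n); P0 <- rep_len(P0, n)
    ks <- numeric(n)
    zero <- !is.na(kdeg) & kdeg == 0
    ks[zero] <- f[zero] * r[zero] * P0[zero] / t
    pos <- !is.na(kdeg) & kdeg > 0
    ks[pos] <- kdeg[pos] * P0[pos] * r[pos] * f[pos] /
        (1 - r[pos] * (1 - f[pos]))
    # f = 0 with kdeg > 0 is pure decay: no synthesis
    ks[pos & f == 0] <- 0
    ks[is.na(kdeg)] <- NA_real_
    ks
}

#' Estimate turnover for every animal and protein fraction of a cohort
#'
#' Runs the full enrichment-to-kinetics pipeline on a [StudyDataset-class]
#' (or on tables in the same schema): natural-abundance correction of each
#' isotopomer distribution, precursor enrichment from plasma body water,
#' fraction-new, then the non-steady-state inversion using each fraction's
#' pool-size marker ratio.
#'
#' The marker policy follows the study conventions: the mitochondrial
#' fraction uses the CoxIV content-marker ratio, the myofibrillar fraction
#' the muscle wet-mass ratio, and the cytosolic fraction (no pool marker)
#' the steady-state estimator. A fraction whose marker column is missing or
#' NA falls back to the steady-state method with a logged downgrade.
#'
#' @param dataset a [StudyDataset-class].
#' @param nSites effective exchangeable hydrogens for the precursor
#'   adjustment (default 3.7).
#' @param method natural-abundance correction mode, "m1" or "matrix".
#' @param markerPolicy named character mapping fraction_id to
#'   \code{"marker"} (use the pool ratio, non-steady) or \code{"steady"}.
#' @param naturalDist baseline isotopomer distribution.
#' @return data.frame with one row per animal x fraction: \code{animal_id},
#'   \code{genotype}, \code{treatment}, \code{fraction_id}, \code{E},
#'   \code{p}, \code{f}, \code{r}, \code{kdeg}, \code{ksyn}, \code{method},
#'   \code{valid}.
#' @seealso [summarizeTurnover()]
#' @examples
#' ds <- simulateCohort(demoGroups(nAnimals = 2), labelingProtocol(),
#'                      noiseModel(seed = 1))
#' head(estimateCohortTurnover(ds))
#' @export
estimateCohortTurnover <- function(dataset, nSites = 3.7,
                                   method = c("m1", "matrix"),
                                   markerPolicy = c(myofibrillar = "marker",
                                                    cytosolic = "steady",
                                                    mitochondrial = "marker"),
                                   naturalDist = naturalIsotopomers()) {
    stopifnot(is(dataset, "StudyDataset"))
    method <- match.arg(method)
    iso <- as.data.frame(isotopomers(dataset))
    ani <- as.data.frame(animals(dataset))
    t <- labelDuration(protocol(dataset))
    mcols <- grep("^M[0-9]+$", colnames(iso), value = TRUE)
    out <- iso[, c("animal_id", "fraction_id")]
    out$genotype <- ani$genotype[match(out$animal_id, ani$animal_id)]
    out$treatment <- ani$treatment[match(out$animal_id, ani$animal_id)]
    bw <- ani$body_water[match(out$animal_id, ani$animal_id)]
    n <- nrow(iso)
    E <- f <- kd <- ks <- p <- numeric(n)
    r <- if ("marker_ratio" %in% colnames(iso)) iso$marker_ratio
         else rep(NA_real_, n)
    meth <- character(n)
    valid <- rep(TRUE, n)
    for (i in seq_len(n)) {
        dist <- isotopomerDistribution(as.numeric(iso[i, mcols]))
        E[i] <- correctNaturalAbundance(dist, naturalDist, method = method)
        pe <- precursorEnrichment(bw[i], nSites)
        p[i] <- pe@p
        fi <- suppressWarnings(fractionNew(E[i], pe))
        f[i] <- fi
        if (is.na(fi) || fi >= 1) { valid[i] <- FALSE; kd[i] <- NA; ks[i] <- NA
            meth[i] <- "invalid"; next }
        policy <- markerPolicy[iso$fraction_id[i]]
        useMarker <- identical(unname(policy), "marker") && !is.na(r[i])
        if (identical(unname(policy), "marker") && is.na(r[i])) {
            .logEvent("method_downgraded")
            useMarker <- FALSE
        }
        if (useMarker) {
            kdi <- suppressWarnings(kdegNonsteady(fi, r[i], t))
            if (is.na(kdi)) { valid[i] <- FALSE; kd[i] <- NA; ks[i] <- NA
                meth[i] <- "invalid"; next }
            kd[i] <- kdi
            ks[i] <- ksynNonsteady(kdi, fi, r[i], 1, t)
            meth[i] <- "non_steady"
        } else {
            kd[i] <- kdegSteady(fi, t)
            ks[i] <- kd[i]   # steady state: ksyn = kdeg * P0, P0 = 1
            meth[i] <- "steady"
        }
    }
    data.frame(out, E = E, p = p, f = f, r = r, kdeg = kd, ksyn = ks,
               method = meth, valid = valid, row.names = NULL)
}

#' Group means and SEMs of turnover estimates
#'
#' @param estimates output of [estimateCohortTurnover()].
#' @return data.frame with one row per genotype x treatment x fraction:
#'   n (valid animals), excluded count, mean and SEM of kdeg and ksyn.
#' @export
summarizeTurnover <- function(estimates) {
    sp <- split(estimates,
                list(estimates$genotype, estimates$treatment,
                     estimates$fraction_id), drop = TRUE)
    rows <- lapply(sp, function(d) {
        ok <- d[d$valid, , drop = FALSE]
        data.frame(genotype = d$genotype[1], treatment = d$treatment[1],
                   fraction_id = d$fraction_id[1],
                   n = nrow(ok), excluded = nrow(d) - nrow(ok),
                   kdeg_mean = mean(ok$kdeg), kdeg_sem = .sem(ok$kdeg),
                   ksyn_mean = mean(ok$ksyn), ksyn_sem = .sem(ok$ksyn))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[order(out$fraction_id, out$genotype, out$treatment), ]
}

.sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
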