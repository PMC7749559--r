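#' @include AllClasses.R
NULL

# package-level run log: counts of clipping/clamping events so that noisy
# samples are never silently altered
.runLog <- new.env(parent = emptyenv())

#' Reset or read the run log of clipping/clamping events
#'
#' The enrichment pipeline never silently drops or alters a sample: every
#' negative-fraction clip, fraction-new clamp and invalid-sample exclusion
#' increments a counter surfaced here and in the pipeline report.
#'
#' @return \code{runLogCounts()} returns a named integer vector;
#'   \code{runLogReset()} zeroes it invisibly.
#' @export
runLogReset <- function() {
    assign("counts", c(isotopomer_clips = 0L, f_clamped = 0L,
                       f_invalid = 0L, E_clamped = 0L, kdeg_invalid = 0L,
                       method_downgraded = 0L),
           envir = .runLog)
    invisible(NULL)
}

#' @rdname runLogReset
#' @export
runLogCounts <- function() get("counts", envir = .runLog)

runLogReset()

.logEvent <- function(what, n = 1L) {
    counts <- get("counts", envir = .runLog)
    counts[what] <- counts[what] + as.integer(n)
    assign("counts", counts, envir = .runLog)
}

.ISOTOPES <- list(
    C = c(`0` = 0.9893,   `1` = 0.0107),
    H = c(`0` = 0.999885, `1` = 0.000115),
    N = c(`0` = 0.99636,  `1` = 0.00364),
    O = c(`0` = 0.99757,  `1` = 0.00038, `2` = 0.00205),
    F = c(`0` = 1),
    S = c(`0` = 0.9499,   `1` = 0.0075, `2` = 0.0425, `4` = 0.0001)
)

#' Natural isotopomer distribution from an elemental composition
#'
#' Convolves the stable-isotope abundance polynomial of each element to give
#' the baseline M0..Mk distribution of an unlabelled molecule. The top bin
#' absorbs all higher mass shifts so the distribution sums to exactly 1.
#' The default composition is the tri-pentafluorobenzyl alanine derivative
#' measured by GC-MS, an assumption documented in the vignette (the
#' derivative chemistry fixes the baseline but cancels out of excess
#' enrichments).
#'
#' @param formula elemental formula string, e.g. \code{"C24H10F15NO2"}.
#' @param k highest tracked mass shift (default 3, i.e. M0..M3).
#' @return an [IsotopomerDistribution-class] of length k + 1.
#' @examples
#' naturalIsotopomers()
#' @export
naturalIsotopomers <- function(formula = "C24H10F15NO2", k = 3L) {
    counts <- .parseFormula(formula)
    dist <- 1
    for (el in names(counts)) {
        iso <- .ISOTOPES[[el]]
        if (is.null(iso)) stop("unknown element: ", el)
        poly <- numeric(max(as.integer(names(iso))) + 1L)
        poly[as.integer(names(iso)) + 1L] <- iso
        for (i in seq_len(counts[[el]])) {
            dist <- .convolve1(dist, poly)
            # drop negligible tail to keep the vector short
            if (length(dist) > k + 4L) {
                tail_mass <- sum(dist[(k + 4L):length(dist)])
                dist <- dist[seq_len(k + 3L)]
                dist[k + 3L] <- dist[k + 3L] + tail_mass
            }
        }
    }
    out <- numeric(k + 1L)
    out[seq_len(min(k, length(dist) - 1L) + 1L)] <-
        dist[seq_len(min(k, length(dist) - 1L) + 1L)]
    out[k + 1L] <- out[k + 1L] + max(0, 1 - sum(out))
    isotopomerDistribution(out)
}

.parseFormula <- function(formula) {
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
    parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
    if (!nzchar(formula) || sum(nchar(parts)) != nchar(formula))
        stop("cannot parse formula: ", formula)
    el <- sub("[0-9]*$", "", parts)
    n <- sub("^[A-Za-z]+", "", parts)
    n <- ifelse(nzchar(n), as.integer(n), 1L)
    tapply(n, el, sum)
}

.convolve1 <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a))
        out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
    out
}

#' Map an excess enrichment onto a measured isotopomer distribution
#'
#' Forward model of the GC-MS observable: a molar excess E of the alanine
#' pool consists of newly synthesised, deuterium-labelled molecules whose
#' spectrum is the natural baseline shifted up one mass unit (single-label
#' approximation of MIDA, valid for body-water enrichments below ~5\%); the
#' remaining (1 - E) of molecules retain the baseline. The top bin absorbs
#' the overflow so the output sums to exactly 1. Optional Gaussian
#' measurement noise is added per channel, negative fractions are clipped
#' to zero (logged in [runLogCounts()]) and the result renormalised.
#'
#' At zero noise, [correctNaturalAbundance()] inverts this mapping exactly.
#'
#' @param E excess enrichment (molar excess of labelled molecules, 0-1).
#' @param nSites effective exchangeable hydrogens of alanine (default 3.7);
#'   not used by the linear single-shift mapping itself — it enters through
#'   the precursor enrichment p = nSites x body water — but kept in the
#'   signature as part of the MIDA configuration.
#' @param naturalDist baseline [IsotopomerDistribution-class] (default
#'   computed from the derivative composition).
#' @param noise a [NoiseModel-class] or NULL for noise-free output. When
#'   \code{isotopomerCV > 0} the per-channel sd is
#'   \code{isotopomerSD + isotopomerCV * E}.
#' @return an [IsotopomerDistribution-class].
#' @examples
#' isotopomerize(0.02)
#' @export
isotopomerize <- function(E, nSites = 3.7, naturalDist = naturalIsotopomers(),
                          noise = NULL) {
    stopifnot(is(naturalDist, "IsotopomerDistribution"))
    if (!is.finite(E) || E < 0 || E > 1)
        stop("'E' must be in [0, 1]")
    N <- isotopomerFractions(naturalDist)
    k <- length(N) - 1L
    shifted <- c(0, N[seq_len(k)])
    shifted[k + 1L] <- shifted[k + 1L] + N[k + 1L]   # absorbing top bin
    obs <- (1 - E) * N + E * shifted
    if (!is.null(noise)) {
        stopifnot(is(noise, "NoiseModel"))
        sd <- noise@isotopomerSD + noise@isotopomerCV * E
        if (sd > 0) {
            obs <- obs + stats::rnorm(length(obs), 0, sd)
            if (any(obs < 0)) {
                .logEvent("isotopomer_clips", sum(obs < 0))
                obs[obs < 0] <- 0
            }
            if (sum(obs) <= 0)
                stop("all isotopomer fractions clipped to zero; noise too large")
            obs <- obs / sum(obs)
        }
    }
    isotopomerDistribution(obs)
}
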