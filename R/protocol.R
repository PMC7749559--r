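#' @include AllClasses.R
NULL

#' Simulate the body-water deuterium enrichment curve
#'
#' One-compartment model of plasma D2O enrichment during a bolus +
#' drinking-water labelling protocol. The bolus equilibrates instantly with
#' the body-water pool, giving an initial enrichment
#' \code{bolusDose * 0.99 / (1000 * bodyWaterPool)}; enrichment then relaxes
#' exponentially, at rate \code{waterTurnover}, toward the plateau implied
#' by the drinking water, \code{waterEnrichment * intakeFraction}.
#' \code{intakeFraction} is the share of body-water input that comes from
#' the labelled drinking water (the remainder — food water and metabolic
#' water — is unlabelled).
#'
#' In real analyses the precursor enrichment is taken from measured plasma;
#' this curve exists so that simulated cohorts carry realistic plasma values.
#'
#' @param protocol a [LabelingProtocol-class].
#' @param times days at which to evaluate the curve; defaults to daily
#'   points over the labelling window.
#' @param intakeFraction fraction of body-water turnover supplied by
#'   drinking water (default 0.55).
#' @param constantPlateau if TRUE, skip the kinetics and return the plateau
#'   value at all times (the "already equilibrated" shortcut).
#' @return data.frame with columns \code{day} and \code{enrichment}
#'   (molar fraction D, in [0, 0.5)).
#' @examples
#' simulateBodyWater(labelingProtocol())
#' @export
simulateBodyWater <- function(protocol, times = NULL, intakeFraction = 0.55,
                              constantPlateau = FALSE) {
    stopifnot(is(protocol, "LabelingProtocol"))
    validObject(protocol)
    if (is.null(times))
        times <- seq(0, protocol@labelDuration, by = 1)
    if (any(times < 0)) stop("'times' must be >= 0 days")
    # bolus: uL/g of 99 atom% D2O into bodyWaterPool mL/g = 1000*pool uL/g
    e0 <- if (protocol@bodyWaterPool > 0)
        protocol@bolusDose * 0.99 / (1000 * protocol@bodyWaterPool) else 0
    eP <- protocol@waterEnrichment * intakeFraction
    enr <- if (constantPlateau) rep(eP, length(times))
           else eP + (e0 - eP) * exp(-protocol@waterTurnover * times)
    if (any(enr >= 0.5))
        stop("simulated body-water enrichment reached 0.5; nonphysical protocol")
    data.frame(day = times, enrichment = enr)
}

#' Time-averaged body-water enrichment over the labelling window
#'
#' The precursor pool seen by newly synthesised protein integrates the
#' plasma curve; the exact time average of the one-compartment solution is
#' used as the effective body-water enrichment of a simulated animal.
#'
#' @inheritParams simulateBodyWater
#' @return single numeric, molar fraction D.
#' @export
meanBodyWater <- function(protocol, intakeFraction = 0.55,
                          constantPlateau = FALSE) {
    stopifnot(is(protocol, "LabelingProtocol"))
    validObject(protocol)
    eP <- protocol@waterEnrichment * intakeFraction
    if (constantPlateau) return(eP)
    e0 <- if (protocol@bodyWaterPool > 0)
        protocol@bolusDose * 0.99 / (1000 * protocol@bodyWaterPool) else 0
    kw <- protocol@waterTurnover
    t <- protocol@labelDuration
    if (kw == 0) return(e0)
    eP + (e0 - eP) * (1 - exp(-kw * t)) / (kw * t)
}
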