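#' @include AllClasses.R
NULL

#' Simulate a first-order protein pool over the labelling window
#'
#' Closed-form solution of the pool model dP/dt = ksyn - kdeg * P:
#' \deqn{P(t) = k_{syn}/k_{deg} + (P_0 - k_{syn}/k_{deg}) e^{-k_{deg} t}}
#' The new-protein mass — protein synthesised during the window that is
#' still present at time t — is
#' \deqn{N(t) = (k_{syn}/k_{deg}) (1 - e^{-k_{deg} t})}
#' so that the surviving original protein is \eqn{P_0 e^{-k_{deg} t}} and
#' \eqn{N(t) + P_0 e^{-k_{deg} t} = P(t)}. The degenerate case kdeg = 0 is
#' the linear-growth limit \eqn{P(t) = P_0 + k_{syn} t}, \eqn{N(t) =
#' k_{syn} t}.
#'
#' @param ksyn synthesis rate, pool units/day (>= 0).
#' @param kdeg degradation rate constant, 1/day (>= 0).
#' @param P0 pool size at label start (> 0); the package convention is
#'   P0 = 1 so that ksyn is in initial-pool fractions per day.
#' @param t labelling time, days (> 0).
#' @return a [PoolTrajectory-class] holding P(t), N(t), the pool ratio
#'   r = P(t)/P0 and the equilibrium pool ksyn/kdeg.
#' @examples
#' simulatePool(ksyn = 0.02, kdeg = 0.049, P0 = 1, t = 5)
#' @export
simulatePool <- function(ksyn, kdeg, P0 = 1, t) {
    stopifnot(length(ksyn) == 1L, length(kdeg) == 1L, length(P0) == 1L,
              length(t) == 1L)
    if (!is.finite(kdeg) || kdeg < 0) stop("'kdeg' must be >= 0")
    if (!is.finite(ksyn) || ksyn < 0) stop("'ksyn' must be >= 0")
    if (!is.finite(P0) || P0 <= 0) stop("'P0' must be > 0")
    if (!is.finite(t) || t <= 0) stop("'t' must be > 0 days")
    if (kdeg == 0) {
        Pt <- P0 + ksyn * t
        Nt <- ksyn * t
        Peq <- if (ksyn == 0) P0 else Inf
    } else {
        Peq <- ksyn / kdeg
        Pt <- Peq + (P0 - Peq) * exp(-kdeg * t)
        Nt <- Peq * (1 - exp(-kdeg * t))
    }
    new("PoolTrajectory", ksyn = ksyn, kdeg = kdeg, P0 = P0, t = t,
        Pt = Pt, Nt = Nt, r = Pt / P0, Peq = Peq)
}

#' Protein-bound alanine excess enrichment of a pool
#'
#' The excess (above natural abundance) enrichment of protein-bound alanine
#' after labelling is the precursor enrichment diluted by the fraction of
#' the pool that is new: \eqn{E = p \cdot N(t)/P(t)}. Only protein made
#' during the window carries label, so E is bounded by p.
#'
#' @param pool a [PoolTrajectory-class].
#' @param precursorP true precursor enrichment p (molar excess, 0-1), from
#'   [precursorEnrichment()].
#' @return excess enrichment E in [0, precursorP].
#' @examples
#' pool <- simulatePool(0.02, 0.049, 1, 5)
#' simulateAlanineEnrichment(pool, precursorP = 0.111)
#' @export
simulateAlanineEnrichment <- function(pool, precursorP) {
    stopifnot(is(pool, "PoolTrajectory"))
    if (!is.finite(precursorP) || precursorP < 0 || precursorP > 1)
        stop("'precursorP' must be in [0, 1]")
    if (pool@Pt <= 0) stop("pool size P(t) must be > 0")
    precursorP * pool@Nt / pool@Pt
}
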