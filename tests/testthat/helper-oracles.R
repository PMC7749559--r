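# Independent numerical oracles used across the suite.

# Numerically integrate the pool model dP/dt = ksyn - kdeg * P together
# with the surviving new-protein mass dN/dt = ksyn - kdeg * N, N(0) = 0.
# Deliberately avoids the closed form the package implements.
odePool <- function(ksyn, kdeg, P0, t) {
  out <- deSolve::lsoda(
    y = c(P = P0, N = 0),
    times = c(0, t),
    func = function(time, y, parms)
      list(c(parms["ksyn"] - parms["kdeg"] * y["P"],
             parms["ksyn"] - parms["kdeg"] * y["N"])),
    parms = c(ksyn = ksyn, kdeg = kdeg),
    rtol = 1e-12, atol = 1e-14)
  list(Pt = out[2, "P"], Nt = out[2, "N"],
       r = out[2, "P"] / P0, f = out[2, "N"] / out[2, "P"])
}

# One-compartment body-water enrichment by numerical integration.
odeBodyWater <- function(e0, eP, kw, times) {
  out <- deSolve::lsoda(
    y = c(E = e0), times = times,
    func = function(time, y, parms) list(parms["kw"] * (parms["eP"] - y["E"])),
    parms = c(kw = kw, eP = eP), rtol = 1e-12, atol = 1e-14)
  out[, "E"]
}

# Exact natural-abundance spectrum of a labelled-molecule mixture at an
# integer number of exchangeable sites: fraction `f` of molecules are new,
# each site deuterated independently with probability `bw`; the rest are
# baseline. The mass spectrum is the label spectrum convolved with the
# baseline, with everything above Mk absorbed into the top bin.
binomialMixtureSpectrum <- function(f, bw, nInt, natural) {
  N <- isotopomerFractions(natural)
  k <- length(N) - 1L
  labelDist <- dbinom(0:nInt, nInt, bw)
  obs <- numeric(k + 1L)
  for (j in 0:nInt) {
    shifted <- numeric(k + 1L)
    for (i in 0:k) {
      m <- min(i + j, k)
      shifted[m + 1L] <- shifted[m + 1L] + N[i + 1L]
    }
    obs <- obs + f * labelDist[j + 1L] * shifted
  }
  obs + (1 - f) * N
}

# Four-group 2x2 design with only the myofibrillar fraction, for kinetic
# recovery simulations; kinetics supplied per group as c(ksyn, kdeg).
myofGroups <- function(kin, nAnimals = 8L, csaN = 2L) {
  design <- list(c("WT", "saline"), c("WT", "LLC"),
                 c("Sod1KO", "saline"), c("Sod1KO", "LLC"))
  lapply(seq_along(design), function(i)
    groupSpec(design[[i]][1], design[[i]][2], nAnimals = nAnimals,
              trueKsyn = c(myofibrillar = kin[[i]][1]),
              trueKdeg = c(myofibrillar = kin[[i]][2]),
              csaN = csaN))
}
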