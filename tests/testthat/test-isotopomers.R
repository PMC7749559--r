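test_that("natural isotopomer baseline matches direct combinatorics", {
  # two carbons, nothing else: M1 = 2 q (1-q), M2 = q^2
  q <- 0.0107
  got <- isotopomerFractions(naturalIsotopomers("C2"))
  expect_equal(unname(got[1]), (1 - q)^2, tolerance = 1e-12)
  expect_equal(unname(got[2]), 2 * q * (1 - q), tolerance = 1e-12)
  expect_equal(unname(got[3]), q^2, tolerance = 1e-12)
  # default derivative baseline is a proper distribution
  def <- isotopomerFractions(naturalIsotopomers())
  expect_equal(sum(def), 1, tolerance = 1e-12)
  expect_true(all(def > 0))
})

test_that("zero enrichment reproduces the baseline exactly", {
  nat <- naturalIsotopomers()
  out <- isotopomerize(0, naturalDist = nat)
  expect_identical(isotopomerFractions(out), isotopomerFractions(nat))
})

test_that("natural-abundance correction inverts the forward model", {
  nat <- naturalIsotopomers()
  for (E in c(0.001, 0.003, 0.01, 0.02, 0.0555, 0.1)) {
    dist <- isotopomerize(E, naturalDist = nat)
    expect_equal(sum(isotopomerFractions(dist)), 1, tolerance = 1e-12)
    expect_lt(abs(correctNaturalAbundance(dist, nat) - E), 1e-10)
    expect_lt(abs(correctNaturalAbundance(dist, nat, method = "matrix") - E),
              1e-10)
  }
})

test_that("distributions stay normalised and clipping is logged under noise", {
  nat <- naturalIsotopomers()
  runLogReset()
  nm <- noiseModel(isotopomerSD = 0.05, seed = 99)
  set.seed(99)
  for (i in 1:50) {
    d <- isotopomerize(0.002, naturalDist = nat, noise = nm)
    expect_equal(sum(isotopomerFractions(d)), 1, tolerance = 1e-12)
    expect_true(all(isotopomerFractions(d) >= 0))
  }
  # sd of 0.05 on an M3 fraction of ~0.003 must have clipped something
  expect_gt(runLogCounts()[["isotopomer_clips"]], 0)
  runLogReset()
})

test_that("single-shift mapping matches the exact binomial mixture", {
  nat <- naturalIsotopomers()
  N <- isotopomerFractions(nat)
  # linear-MIDA statement: M1 excess equals E * (N0 - N1)
  E <- 0.02
  d <- isotopomerize(E, nSites = 3.7, naturalDist = nat)
  expect_equal(isotopomerFractions(d)[["M1"]] - N[["M1"]], E * (N[[1]] - N[[2]]),
               tolerance = 1e-14)
  # exact integer-site oracle: f new molecules, each of 4 sites labelled
  # with probability bw; molar excess (mean label number) is f * 4 * bw
  f <- 0.4; bw <- 0.0135; nInt <- 4L
  obs <- binomialMixtureSpectrum(f, bw, nInt, nat)
  expect_equal(sum(obs), 1, tolerance = 1e-12)
  Ehat <- correctNaturalAbundance(isotopomerDistribution(obs), nat,
                                  method = "matrix")
  expect_lt(abs(Ehat - f * nInt * bw) / (f * nInt * bw), 0.07)
  # and the M1-based estimate agrees with the matrix estimate to the same bound
  Em1 <- correctNaturalAbundance(isotopomerDistribution(obs), nat)
  expect_lt(abs(Em1 - f * nInt * bw) / (f * nInt * bw), 0.07)
})

test_that("a measured distribution below baseline clamps E to zero", {
  nat <- naturalIsotopomers()
  N <- isotopomerFractions(nat)
  low <- N; low[2] <- low[2] - 0.001; low[1] <- low[1] + 0.001
  runLogReset()
  expect_equal(correctNaturalAbundance(isotopomerDistribution(low), nat), 0)
  expect_gt(runLogCounts()[["E_clamped"]], 0)
  runLogReset()
})
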