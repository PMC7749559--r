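test_that("identical seed and configuration give a bit-identical dataset", {
  groups <- demoGroups(nAnimals = 3L)
  nm <- noiseModel(isotopomerSD = 3e-4, poolMarkerCV = 0.05, ctSD = 0.2,
                   seed = 123)
  ds1 <- simulateCohort(groups, labelingProtocol(), nm)
  ds2 <- simulateCohort(groups, labelingProtocol(), nm)
  expect_identical(serialize(as.data.frame(animals(ds1)), NULL),
                   serialize(as.data.frame(animals(ds2)), NULL))
  expect_identical(serialize(as.data.frame(isotopomers(ds1)), NULL),
                   serialize(as.data.frame(isotopomers(ds2)), NULL))
  expect_identical(serialize(as.data.frame(fiberAreas(ds1)), NULL),
                   serialize(as.data.frame(fiberAreas(ds2)), NULL))
  # different seed changes the noisy columns
  ds3 <- simulateCohort(groups, labelingProtocol(),
                        noiseModel(isotopomerSD = 3e-4, poolMarkerCV = 0.05,
                                   ctSD = 0.2, seed = 124))
  expect_false(identical(as.data.frame(isotopomers(ds1)),
                         as.data.frame(isotopomers(ds3))))
})

test_that("with every stochastic scale at zero all animals are identical", {
  g <- groupSpec("WT", "saline", nAnimals = 4L,
                 trueKsyn = c(myofibrillar = 0.01),
                 trueKdeg = c(myofibrillar = 0.02),
                 sdConductionVelocity = 0, csaSdLog = 0, csaN = 3L)
  ds <- simulateCohort(list(g), labelingProtocol(), noiseModel(seed = 1))
  ani <- as.data.frame(animals(ds))
  iso <- as.data.frame(isotopomers(ds))
  for (col in setdiff(colnames(ani), "animal_id"))
    expect_length(unique(ani[[col]]), 1)
  for (col in setdiff(colnames(iso), "animal_id"))
    expect_length(unique(iso[[col]]), 1)
  expect_length(unique(as.data.frame(fiberAreas(ds))$area), 1)
})

test_that("duplicate group labels are rejected", {
  g <- demoGroups(nAnimals = 2L)
  expect_error(simulateCohort(g[c(1, 1)], labelingProtocol(),
                              noiseModel(seed = 1)), "duplicate")
})

test_that("distinct planted rates are recovered per group, noise-free", {
  kin <- list(c(0.00847, 0.00847), c(0.010, 0.0211),
              c(0.018, 0.018), c(0.020, 0.049))
  ds <- simulateCohort(myofGroups(kin, nAnimals = 4L), labelingProtocol(),
                       noiseModel(seed = 10))
  est <- estimateCohortTurnover(ds)
  sm <- summarizeTurnover(est)
  truthMap <- data.frame(
    genotype = c("WT", "WT", "Sod1KO", "Sod1KO"),
    treatment = c("saline", "LLC", "saline", "LLC"),
    kdeg = c(0.00847, 0.0211, 0.018, 0.049))
  m <- merge(sm, truthMap, by = c("genotype", "treatment"))
  expect_equal(m$kdeg_mean, m$kdeg, tolerance = 1e-9)
  expect_true(all(m$kdeg_sem < 1e-12))
})

test_that("write/read round trip preserves the analysis", {
  dir <- withr::local_tempdir()
  ds <- simulateCohort(demoGroups(nAnimals = 2L), labelingProtocol(),
                       noiseModel(isotopomerSD = 1e-4, seed = 3))
  writeStudyDataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
      c("animals.csv", "isotopomers.csv", "fiber_csa.csv", "truth.csv",
        "config.yaml", "run.log")))))
  ds2 <- readStudyDataset(dir)
  est1 <- estimateCohortTurnover(ds)
  est2 <- estimateCohortTurnover(ds2)
  expect_equal(est1$kdeg, est2$kdeg, tolerance = 1e-12)
  expect_equal(est1$method, est2$method)
})
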