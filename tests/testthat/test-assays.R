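makeCtPanel <- function(dct) {
  # two groups; calibrator animals have target dCt = 5, test animal dCt set
  # so its ddCt equals `dct`
  data.frame(
    animal_id = rep(c("c1", "c2", "x1"), each = 2),
    group = rep(c("cal", "cal", "test"), each = 2),
    gene = rep(c("Runx1", "Rn18s"), 3),
    ct = c(17, 12, 17, 12, 17 + dct, 12))
}

test_that("ddCt maps cycle differences to fold changes", {
  expect_equal(ddct(makeCtPanel(0), calibratorGroup = "cal")$rq[3], 1)
  expect_equal(ddct(makeCtPanel(1), calibratorGroup = "cal")$rq[3], 0.5)
  expect_equal(ddct(makeCtPanel(-2), calibratorGroup = "cal")$rq[3], 4)
  # calibrator group mean relative quantity is 1 on the log2 scale
  out <- ddct(makeCtPanel(1), calibratorGroup = "cal")
  expect_equal(mean(log2(out$rq[out$group == "cal"])), 0, tolerance = 1e-12)
})

test_that("ddCt is invariant to a constant shift of an animal's panel", {
  ct <- makeCtPanel(1)
  shifted <- ct
  shifted$ct[shifted$animal_id == "x1"] <- shifted$ct[shifted$animal_id == "x1"] + 3
  expect_equal(ddct(ct, calibratorGroup = "cal")$rq,
               ddct(shifted, calibratorGroup = "cal")$rq)
})

test_that("animals without the reference gene are excluded with a warning", {
  ct <- makeCtPanel(1)
  ct <- ct[!(ct$animal_id == "x1" & ct$gene == "Rn18s"), ]
  expect_warning(out <- ddct(ct, calibratorGroup = "cal"), "reference")
  expect_false("x1" %in% out$animal_id)
  expect_error(ddct(makeCtPanel(0), calibratorGroup = "nope"), "calibrator")
})

test_that("respirometry normalisation subtracts antimycin A per mg", {
  tr <- c(state1 = 2, GM = 6, CI = 12, antimycinA = 2, TMPD = 20)
  out <- normalizeOcr(tr, wetWeight = 2)
  expect_equal(unname(out["state1"]), 0)
  expect_equal(unname(out["CI"]), 5)
  expect_equal(unname(out["TMPD"]), 9)
  expect_false("antimycinA" %in% names(out))
  # TMPD exemption flag
  out2 <- normalizeOcr(tr, wetWeight = 2, subtractTMPD = FALSE)
  expect_equal(unname(out2["TMPD"]), 10)
  # linearity in the input flux
  tr3 <- tr; tr3[c("GM", "CI")] <- tr3[c("GM", "CI")] * 3
  out3 <- normalizeOcr(tr3, wetWeight = 2)
  expect_equal(unname(out3["CI"] - out3["GM"]),
               3 * unname(out["CI"] - out["GM"]))
  # sub-floor states clamp with a warning
  expect_warning(out4 <- normalizeOcr(c(state1 = 1, antimycinA = 2), 1),
                 "clamped")
  expect_equal(unname(out4["state1"]), 0)
  expect_error(normalizeOcr(c(state1 = 1), 1), "antimycinA")
})

test_that("planted mitochondrial flux is recovered from a simulated trace", {
  mito <- c(state1 = 3, GM = 18, CI = 35, `CI+II` = 52, CII = 25)
  background <- 4; weight <- 2.5
  raw <- c(mito + background, antimycinA = background) * weight
  # raw fluxes scale with wet weight; normalisation must undo both
  out <- normalizeOcr(raw / weight * weight, wetWeight = weight)
  expect_equal(out[names(mito)], mito, tolerance = 1e-12)
})

test_that("fibre areas partition into the published size bins", {
  expect_equal(unname(binFiberCsa(1200)$counts["small"]), 1L)
  expect_equal(unname(binFiberCsa(2400.1)$counts["large"]), 1L)
  expect_equal(unname(binFiberCsa(2400)$counts["average"]), 1L)
  expect_equal(unname(binFiberCsa(150)$counts["subthreshold"]), 1L)
  empty <- binFiberCsa(numeric(0))
  expect_equal(sum(empty$counts), 0L)
  # conservation against direct enumeration on a uniform sample
  set.seed(31)
  areas <- runif(5000, 200, 3000)
  got <- binFiberCsa(areas)
  expect_equal(unname(got$counts["small"]), sum(areas <= 1200))
  expect_equal(unname(got$counts["large"]), sum(areas > 2400))
  expect_equal(sum(got$counts[c("small", "average", "large")]),
               length(areas))
  expect_equal(sum(got$frequency), 1)
})

test_that("muscle mass is normalised to tumour-free body weight", {
  expect_equal(normalizeMass(100, 25, 0), 4)
  expect_equal(normalizeMass(100, 25, 5), 5)
  expect_error(normalizeMass(100, 25, 25), "smaller")
  expect_error(normalizeMass(100, 25, -1), ">= 0")
  # percent-loss table matches direct computation on a small cohort
  mm <- c(95, 80); bw <- c(24, 23); tw <- c(0, 2)
  norm <- normalizeMass(mm, bw, tw)
  expect_equal(norm, mm / (bw - tw))
})
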