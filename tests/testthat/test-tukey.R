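test_that("studentized range tail is a proper survival function", {
  expect_equal(studentizedRangeSF(0, 4, 20), 1)
  qs <- seq(0.5, 6, by = 0.5)
  ps <- studentizedRangeSF(qs, 4, 20)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(studentizedRangeSF(2, 2.5, 10), "integer")
  expect_error(studentizedRangeSF(-1, 3, 10), "q")
})

test_that("k = 2 reduces to the two-sided t tail via q = sqrt(2) t", {
  for (df in c(5, 14, 30)) {
    for (q in c(0.5, 1.5, 2.8, 4)) {
      expect_equal(studentizedRangeSF(q, 2, df),
                   2 * pt(q / sqrt(2), df, lower.tail = FALSE),
                   tolerance = 1e-7)
    }
  }
})

test_that("numerical integration agrees with R's ptukey", {
  grid <- expand.grid(q = c(1, 2.5, 3.96, 5.5), k = c(3, 4, 6),
                      df = c(8, 20, 60))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(studentizedRangeSF(g$q, g$k, g$df),
                 ptukey(g$q, g$k, g$df, lower.tail = FALSE),
                 tolerance = 1e-6)
  }
})

test_that("tail matches a simulated studentized-range null", {
  set.seed(17)
  nrep <- 2e5
  z <- matrix(rnorm(nrep * 4), nrep, 4)
  s <- sqrt(rchisq(nrep, 20) / 20)
  qnull <- (apply(z, 1, max) - apply(z, 1, min)) / s
  for (q in c(3, 3.96)) {
    pMC <- mean(qnull > q)
    ci <- 3 * sqrt(pMC * (1 - pMC) / nrep)
    expect_lt(abs(studentizedRangeSF(q, 4, 20) - pMC), ci + 1e-3)
  }
})

makeTwoCellResult <- function(y1, y2) {
  # a minimal two-cell AnovaResult so the Kramer path can be exercised at
  # k = 2 (one factor, two groups)
  n1 <- length(y1); n2 <- length(y2)
  mse <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) / (n1 + n2 - 2)
  new("AnovaResult",
      terms = data.frame(term = c("group", "residual"),
                         df = c(1, n1 + n2 - 2),
                         SS = c(NA, mse * (n1 + n2 - 2)),
                         MS = c(NA, mse), F = c(30, NA), p = c(1e-4, NA)),
      cellMeans = data.frame(group = c("g1", "g2"),
                             mean = c(mean(y1), mean(y2)), n = c(n1, n2)),
      mse = mse, dfResidual = n1 + n2 - 2, ssTotal = NA_real_,
      ssType = "II", factorNames = c("group", "none"), degenerate = FALSE)
}

test_that("two-group Tukey-Kramer equals the pooled t-test", {
  set.seed(4)
  y1 <- rnorm(8, 0); y2 <- rnorm(6, 1.5)
  res <- tukeyKramer(makeTwoCellResult(y1, y2), force = TRUE)
  ref <- t.test(y1, y2, var.equal = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-6)
  expect_equal(res$q, sqrt(2) * abs(unname(ref$statistic)), tolerance = 1e-9)
})

test_that("identical group means give p of 1 for every pair", {
  set.seed(9)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:4)
  d$y <- rnorm(nrow(d))
  d$y <- d$y - ave(d$y, paste(d$A, d$B))  # force all cell means to zero
  fit <- twoWayAnova(d$y, d$A, d$B)
  cmp <- tukeyKramer(fit, force = TRUE)
  expect_equal(nrow(cmp), 6)
  expect_true(all(abs(cmp$p - 1) < 1e-9))
})

test_that("post hoc is gated on a significant F ratio", {
  set.seed(5)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:6)
  d$y <- rnorm(nrow(d))
  d$y <- d$y - ave(d$y, paste(d$A, d$B))  # exact null: equal cell means
  fit <- twoWayAnova(d$y, d$A, d$B)
  expect_false(any(anovaTable(fit)$p < 0.05, na.rm = TRUE))
  expect_message(cmp <- tukeyKramer(fit), "not performed")
  expect_equal(nrow(cmp), 0)
  expect_equal(nrow(tukeyKramer(fit, force = TRUE)), 6)
})

test_that("Kramer weights agree with TukeyHSD on balanced data", {
  set.seed(6)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:6)
  d$y <- rnorm(nrow(d)) + 2 * (d$A == "a2") + (d$B == "b2")
  fit <- twoWayAnova(d$y, d$A, d$B)
  cmp <- tukeyKramer(fit, force = TRUE)
  ref <- TukeyHSD(aov(y ~ A:B, data = d))[["A:B"]]
  # match pairs by absolute mean difference
  expect_equal(sort(abs(cmp$diff)), unname(sort(abs(ref[, "diff"]))),
               tolerance = 1e-9)
  expect_equal(sort(cmp$p), unname(sort(ref[, "p adj"])), tolerance = 1e-5)
})
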