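# balanced 2x2, n = 3 per cell, constructed from known effects
balancedToy <- function() {
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
  resid <- c(1, -1, 0, 2, -2, 0, 1, 0, -1, -1, 1, 0)  # sums to 0 per cell? no: kept integer
  eff <- 10 + 2 * (d$A == "a2") + 1 * (d$B == "b2") +
    0.5 * (d$A == "a2" & d$B == "b2")
  d$y <- eff + resid
  d
}

test_that("balanced decomposition matches hand-computed cell means", {
  d <- balancedToy()
  fit <- twoWayAnova(d$y, d$A, d$B)
  # brute-force oracle from first principles
  gm <- mean(d$y)
  mA <- tapply(d$y, d$A, mean); mB <- tapply(d$y, d$B, mean)
  mAB <- tapply(d$y, list(d$A, d$B), mean)
  ssA <- 6 * sum((mA - gm)^2)
  ssB <- 6 * sum((mB - gm)^2)
  ssAB <- 3 * sum((mAB - outer(mA, mB, `+`) + gm)^2)
  ssE <- sum((d$y - mAB[cbind(d$A, d$B)])^2)
  tab <- anovaTable(fit)
  expect_equal(tab$SS, c(ssA, ssB, ssAB, ssE), tolerance = 1e-12)
  expect_equal(tab$df, c(1, 1, 1, 8))
  # partition conservation, exact on balanced data
  expect_equal(sum(tab$SS), fit@ssTotal, tolerance = 1e-12)
})

test_that("aov agrees with the balanced fast path", {
  d <- balancedToy()
  fit <- twoWayAnova(d$y, d$A, d$B)
  ref <- summary(aov(y ~ A * B, data = d))[[1]]
  expect_equal(anovaTable(fit)$SS, ref$`Sum Sq`, tolerance = 1e-10)
  expect_equal(anovaTable(fit)$F[1:3], ref$`F value`[1:3], tolerance = 1e-10)
  expect_equal(anovaTable(fit)$p[1:3], ref$`Pr(>F)`[1:3], tolerance = 1e-10)
})

test_that("adding a constant leaves F and p unchanged", {
  d <- balancedToy()
  f1 <- anovaTable(twoWayAnova(d$y, d$A, d$B))
  f2 <- anovaTable(twoWayAnova(d$y + 100, d$A, d$B))
  expect_equal(f1$F, f2$F, tolerance = 1e-10)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("a constant response is reported as degenerate, not NaN", {
  d <- balancedToy()
  fit <- twoWayAnova(rep(3, nrow(d)), d$A, d$B)
  expect_true(isDegenerate(fit))
  expect_true(all(is.na(anovaTable(fit)$F)))
  expect_true(all(is.na(anovaTable(fit)$p)))
  expect_equal(fit@ssTotal, 0)
})

test_that("empty design cells are rejected with a clear message", {
  d <- balancedToy()
  drop <- !(d$A == "a2" & d$B == "b2")
  expect_error(twoWayAnova(d$y[drop], d$A[drop], d$B[drop]), "empty")
  expect_error(twoWayAnova(d$y, d$A, rep("b1", nrow(d))), "2 levels")
})

test_that("unbalanced Type II and III match the car reference", {
  skip_if_not_installed("car")
  set.seed(8)
  d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:8)
  d$y <- rnorm(nrow(d)) + 1.2 * (d$A == "a2") + 0.8 * (d$B == "b2")
  d <- d[-c(1, 2, 5), ]  # unbalance: n = 6-8 per cell like the study
  for (type in c("II", "III")) {
    fit <- twoWayAnova(d$y, d$A, d$B, ssType = type)
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    ref <- car::Anova(lm(y ~ A * B, data = d), type = type)
    options(op)
    tab <- anovaTable(fit)
    idx <- if (type == "III") 2:5 else 1:4  # type III reports an intercept row
    expect_equal(tab$SS, ref$`Sum Sq`[idx], tolerance = 1e-9, info = type)
    expect_equal(tab$p[1:3], ref$`Pr(>F)`[idx[1:3]], tolerance = 1e-9,
                 info = type)
  }
})
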