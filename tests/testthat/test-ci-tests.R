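test_that("the Welch t-test matches the reference implementation", {
  set.seed(1)
  for (r in 1:5) {
    a <- rep(0:1, times = c(40, 60))
    x <- rnorm(100) + 0.3 * a
    got <- tTestMarginal(x, a)
    ref <- t.test(x[a == 1], x[a == 0])
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }

  # power: unit mean shift at n = 500 per group is overwhelming
  set.seed(2)
  a <- rep(0:1, each = 500)
  x <- rnorm(1000, mean = a)
  expect_lt(tTestMarginal(x, a)$p.value, 1e-6)

  # identical values in both groups: statistic 0, p = 1
  v <- rnorm(50)
  expect_equal(tTestMarginal(c(v, v), rep(0:1, each = 50))$statistic, 0)
  expect_equal(tTestMarginal(c(v, v), rep(0:1, each = 50))$p.value, 1)

  # degenerate groupings are refused
  expect_error(tTestMarginal(rnorm(10), rep(1, 10)), "degenerate")
  expect_error(tTestMarginal(rep(c(0, 2), each = 10), rep(0:1, each = 10)),
               "zero within-group variance")
})

test_that("the Fisher z statistic follows its closed form", {
  # construct vectors with sample correlation exactly 0.5:
  # statistic = atanh(0.5) * sqrt(97), p ~ 6.3e-8
  set.seed(3)
  n <- 100
  x <- as.numeric(scale(rnorm(n)))
  e <- residuals(lm(rnorm(n) ~ x))
  e <- as.numeric(scale(e))
  y <- 0.5 * x + sqrt(1 - 0.25) * e
  got <- fisherZTest(x, y)
  expect_equal(got$statistic, atanh(0.5) * sqrt(97), tolerance = 1e-10)
  expect_equal(got$p.value, 6.3e-8, tolerance = 0.01)

  # perfect dependence
  expect_warning(res <- fisherZTest(x, x), "perfect")
  expect_equal(res$p.value, 0)

  # mediation x -> z -> y: marginal dependence rejected, conditional
  # independence accepted in most repetitions
  accepted <- 0
  rejectedMarginal <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(5000)
    z <- 0.8 * x + rnorm(5000)
    y <- 0.8 * z + rnorm(5000)
    if (fisherZTest(x, y)$p.value < 0.001) rejectedMarginal <- rejectedMarginal + 1
    if (fisherZTest(x, y, z = z)$p.value > 0.15) accepted <- accepted + 1
  }
  expect_equal(rejectedMarginal, 100)
  # under exact uniformity P(p > 0.15) = 0.85; allow binomial spread
  expect_gte(accepted, 72)

  # collinear conditioning set
  z1 <- rnorm(50)
  expect_error(fisherZTest(rnorm(50), rnorm(50), z = cbind(z1, 2 * z1)),
               "collinear")
  expect_error(fisherZTest(rnorm(3), rnorm(3)), "too few")
})

test_that("the logistic likelihood-ratio test is calibrated and powered", {
  # a <- z structure, x depends on z only: a _||_ x | z
  set.seed(4)
  pvals <- replicate(200, {
    z <- rnorm(400)
    a <- rbinom(400, 1, plogis(z))
    x <- z + rnorm(400)
    logisticLRTest(a, x, z = z)$p.value
  })
  # roughly uniform: mean near 0.5 and no mass collapse at 0
  expect_gt(mean(pvals), 0.4)
  expect_lt(mean(pvals), 0.6)
  expect_lt(mean(pvals < 0.05), 0.12)

  # direct dependence: slope 1 logit model at n = 2000
  set.seed(5)
  x <- rnorm(2000)
  a <- rbinom(2000, 1, plogis(x))
  expect_lt(logisticLRTest(a, x)$p.value, 1e-6)

  # constant x carries no information
  res <- logisticLRTest(rep(0:1, 50), rep(2, 100))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  # perfect separation is an error unless explicitly allowed
  xs <- c(rnorm(50, -5), rnorm(50, 5))
  as <- rep(0:1, each = 50)
  expect_error(logisticLRTest(as, xs), "separation")
  expect_equal(logisticLRTest(as, xs, allowSeparation = TRUE)$p.value, 0)

  # Wald variant agrees in order of magnitude with the LR variant
  set.seed(6)
  x <- rnorm(1000)
  a <- rbinom(1000, 1, plogis(0.5 * x))
  pLR <- logisticLRTest(a, x)$p.value
  pW <- logisticLRTest(a, x, type = "wald")$p.value
  expect_lt(abs(log10(pLR) - log10(pW)), 1)
})

test_that("p-values are invariant to affine rescaling and label swaps", {
  set.seed(7)
  a <- rep(0:1, each = 100)
  x <- rnorm(200) + 0.4 * a
  y <- rnorm(200) + 0.5 * x
  resc <- function(v) 3.7 * v - 11
  expect_equal(tTestMarginal(resc(x), a)$p.value,
               tTestMarginal(x, a)$p.value, tolerance = 1e-9)
  expect_equal(fisherZTest(resc(x), resc(y), z = a)$p.value,
               fisherZTest(x, y, z = a)$p.value, tolerance = 1e-9)
  expect_equal(logisticLRTest(a, resc(x), z = y)$p.value,
               logisticLRTest(a, x, z = y)$p.value, tolerance = 1e-6)

  swapped <- tTestMarginal(x, 1L - a)
  original <- tTestMarginal(x, a)
  expect_equal(swapped$statistic, -original$statistic, tolerance = 1e-12)
  expect_equal(swapped$p.value, original$p.value, tolerance = 1e-12)
})

test_that("the dual-threshold rule is correct and monotone", {
  th <- ciThresholds()
  expect_equal(th$alpha, 0.001)
  expect_equal(th$beta, 0.15)
  expect_equal(ciDecide(0.0005, th), "dependent")
  expect_equal(ciDecide(0.5, th), "independent")
  expect_equal(ciDecide(0.05, th), "uncertain")
  expect_error(ciThresholds(0.2, 0.1), "alpha < beta")

  # lowering alpha never turns an independent call into a dependent one
  ps <- c(1e-6, 1e-4, 0.01, 0.2, 0.9)
  for (p in ps) {
    d1 <- ciDecide(p, ciThresholds(1e-3, 0.15))
    d2 <- ciDecide(p, ciThresholds(1e-5, 0.15))
    if (d1 == "independent") expect_false(d2 == "dependent")
    if (d2 == "dependent") expect_equal(d1, "dependent")
  }
})
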