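test_that("random models honour structural invariants and densities", {
  # empty graph: density 0, one activator target
  m0 <- makeRandomModel(3, edgeDensity = 0, confounderDensity = 0,
                        activatorOutDegree = 1, seed = 1)
  expect_true(all(connectivity(m0) == 0))
  expect_equal(sum(activatorEffects(m0) != 0), 1)

  # full-density acyclic graph: exactly p(p-1)/2 edges forming a total order
  m1 <- makeRandomModel(3, edgeDensity = 1, seed = 2)
  expect_equal(sum(connectivity(m1) != 0), 3L)
  expect_false(is.null(cytocausal:::.topologicalOrder(connectivity(m1))))

  # p = 14: stable and invertible for several seeds, panel names attached
  for (s in 1:5) {
    m <- makeRandomModel(14, edgeDensity = 0.15, confounderDensity = 0.05,
                         cyclic = TRUE, seed = s)
    B <- connectivity(m)
    expect_lt(max(Mod(eigen(B, only.values = TRUE)$values)), 1)
    expect_gt(abs(det(diag(14) - B)), 1e-12)
  }
  expect_true("pZap70" %in% markerNames(makeRandomModel(14, seed = 1)))

  expect_error(makeRandomModel(1), "at least p = 2")
})

test_that("equilibrium covariance matches the closed form", {
  # 2-variable chain b21 = 0.5: covariance [[1, 0.5], [0.5, 1.25]]
  B <- matrix(c(0, 0.5, 0, 0), 2, 2)
  m <- causalModel(B)
  expect_equal(unname(populationCovariance(m)),
               matrix(c(1, 0.5, 0.5, 1.25), 2, 2))

  # intervention variance 1 on variable 1 doubles var(x1) and propagates
  Sc <- populationCovariance(m, interventionVariances = c(1, 0))
  expect_equal(unname(Sc), matrix(c(2, 1, 1, 1.5), 2, 2))

  # sample covariance converges to the population one (3 standard errors
  # at n = 50,000; se of a covariance entry is O(1/sqrt(n)))
  n <- 50000
  tab <- simulateCondition(m, n = n, seed = 99)
  S <- cov(cellValues(tab))
  tol <- 3 * sqrt(2 * 1.25^2 / n) # conservative bound over entries
  expect_lt(max(abs(S - populationCovariance(m))), tol)

  # identity case
  m0 <- causalModel(matrix(0, 2, 2))
  S0 <- cov(cellValues(simulateCondition(m0, n = n, seed = 7)))
  expect_lt(max(abs(S0 - diag(2))), tol)

  # activator shifts only its downstream targets
  mA <- causalModel(B, a = c(1, 0))
  on <- simulateCondition(mA, activated = TRUE, n = 20000, seed = 3)
  off <- simulateCondition(mA, activated = FALSE, n = 20000, seed = 4)
  shift <- colMeans(cellValues(on)) - colMeans(cellValues(off))
  expect_equal(unname(shift), c(1, 0.5), tolerance = 0.05)
})

test_that("fixed seeds reproduce studies byte-identically", {
  m <- chainModel3()
  design <- makeStudyDesign(m, nActivators = 2, nInhibitors = 3,
                            nDosages = 2, nPerCondition = c(8, 50), seed = 5)
  b1 <- simulateStudy(m, design, seed = 42)
  b2 <- simulateStudy(m, design, seed = 42)
  expect_identical(conditionKeys(b1), conditionKeys(b2))
  for (k in conditionKeys(b1))
    expect_identical(cellValues(studyTables(b1)[[k]]),
                     cellValues(studyTables(b2)[[k]]))
  b3 <- simulateStudy(m, design, seed = 43)
  expect_false(identical(cellValues(studyTables(b1)[[1]]),
                         cellValues(studyTables(b3)[[1]])))
})

test_that("acyclic ancestry agrees with the mixing-matrix pattern", {
  for (s in 1:5) {
    m <- makeRandomModel(6, edgeDensity = 0.4, seed = s)
    B <- connectivity(m)
    Minv <- solve(diag(6) - B)
    # reachability: j is an ancestor of i iff sum_k B^k has (i, j) != 0
    reach <- diag(6)
    Bk <- diag(6)
    for (k in 1:6) {
      Bk <- Bk %*% B
      reach <- reach + abs(Bk)
    }
    expect_identical(unname(abs(Minv) > 1e-12), unname(reach > 1e-12))
  }
})

test_that("study layout reproduces the perturbation design", {
  m <- chainModel3()
  # dose-zero-only design: one activated + one reference table per plate
  d1 <- makeStudyDesign(m, nActivators = 1, nInhibitors = 27, nDosages = 1,
                        nPerCondition = 25, seed = 1)
  b1 <- simulateStudy(m, d1, seed = 1)
  acts <- vapply(studyTables(b1), function(tab) cellMeta(tab)$activator, "")
  expect_equal(sum(acts == "act1"), 27L)
  expect_equal(sum(acts == "reference"), 27L)

  # dose-zero tables are exchangeable draws from one distribution:
  # population covariance identical, means equal within noise
  k1 <- cellValues(getCondition(b1, "pop1", "reference", "inh1", 0))
  k2 <- cellValues(getCondition(b1, "pop1", "reference", "inh2", 0))
  expect_false(identical(k1, k2))

  # dosage ladder: 8 environments for one activator/inhibitor context
  d2 <- makeStudyDesign(m, nActivators = 1, nInhibitors = 1, nDosages = 8,
                        nPerCondition = 30, seed = 2)
  b2 <- simulateStudy(m, d2, seed = 2)
  doses <- vapply(studyTables(b2), function(tab) cellMeta(tab)$dosage, 0L)
  expect_setequal(unique(doses), 0:7)
  expect_equal(length(b2), 16L) # (reference + act1) x 8 dosages

  # a zero-cell condition is dropped with a message
  d3 <- d1
  d3$inhibitors <- d1$inhibitors[1:2]
  d3$nPerCondition <- function(key) if (grepl("inh2", key)) 0 else 25
  expect_message(b3 <- simulateStudy(m, d3, seed = 3), "dropped")
  expect_false(any(grepl("inh2", conditionKeys(b3))))

  # empty design is rejected
  expect_error(simulateStudy(m, list(), seed = 1), "empty design")
})

test_that("studies round-trip through CSV + manifest", {
  m <- chainModel3()
  design <- makeStudyDesign(m, nActivators = 1, nInhibitors = 2,
                            nDosages = 2, nPerCondition = 21, seed = 5)
  b <- simulateStudy(m, design, seed = 11)
  dir <- withr::local_tempdir()
  writeStudy(b, dir)
  b2 <- readStudy(dir)
  expect_identical(conditionKeys(b), conditionKeys(b2))
  for (k in conditionKeys(b)) {
    expect_lt(max(abs(cellValues(studyTables(b)[[k]]) -
                        cellValues(studyTables(b2)[[k]]))), 1e-7)
    expect_identical(cellMeta(studyTables(b)[[k]]),
                     cellMeta(studyTables(b2)[[k]]))
  }
  expect_identical(b2@modelHash, b@modelHash)

  # marker mismatch against the manifest names the offending file
  victim <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)[1]
  df <- read.csv(victim, check.names = FALSE)
  write.csv(df[, -1], victim, row.names = FALSE, quote = FALSE)
  expect_error(readStudy(dir), basename(victim), fixed = TRUE)

  # a directory without a manifest is refused
  expect_error(readStudy(withr::local_tempdir()), "manifest")
})

test_that("a study coerces to a SummarizedExperiment", {
  m <- chainModel3()
  design <- makeStudyDesign(m, nActivators = 1, nInhibitors = 2,
                            nDosages = 1, nPerCondition = 10, seed = 1)
  b <- simulateStudy(m, design, seed = 1)
  se <- asSummarizedExperiment(b)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(3L, 40L))
  expect_true(all(c("subpopulation", "activator", "inhibitor", "dosage") %in%
                    colnames(SummarizedExperiment::colData(se))))
})
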