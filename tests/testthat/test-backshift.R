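test_that("environment covariances are validated and consistent", {
  set.seed(1)
  X <- matrix(rnorm(10000 * 3), ncol = 3,
              dimnames = list(NULL, paste0("P", 1:3)))
  env <- environmentCovariances(list(X, X + 0))
  expect_lt(max(abs(env$covariances[[1]] - diag(3))), 0.1)

  # duplicating rows leaves the estimate essentially unchanged
  env2 <- environmentCovariances(list(rbind(X, X)))
  expect_lt(max(abs(env2$covariances[[1]] - env$covariances[[1]])), 1e-4)

  # n = p is too small
  expect_error(environmentCovariances(list(X[1:3, ])), "at least p \\+ 1")

  # constant marker named in the error
  Xc <- X
  Xc[, 2] <- 5
  expect_error(environmentCovariances(list(Xc)), "P2")
})

test_that("joint diagonalization recovers known mixing structures", {
  # already-diagonal input: identity diagonalizer, zero residual
  diffs <- list(diag(c(1, 2, 3)) - diag(2, 3), diag(c(3, 1, 0.5)) - diag(1.5, 3))
  jd <- jointDiagonalize(diffs)
  expect_lt(jd$residual, 1e-20)
  expect_equal(unname(jd$W), diag(3) / sqrt(1), tolerance = 1e-10)

  # population covariance differences from a known acyclic model:
  # assignment + rescaling returns B exactly
  m <- acyclicModel3()
  B <- connectivity(m)
  covs <- lapply(list(c(1, 2, 3), c(3, 1, 0.5), c(0.2, 4, 1), c(0, 0, 0)),
                 function(v) populationCovariance(m, v))
  avg <- Reduce(`+`, covs) / length(covs)
  jd2 <- jointDiagonalize(lapply(covs, function(S) S - avg))
  expect_lt(jd2$residual, 1e-10)
  Bhat <- resolveScalePermutation(jd2$W)
  expect_lt(max(abs(Bhat - B)), 1e-6)

  # an intervention on a hidden parent leaves a residual bounded away
  # from zero: the violation is visible
  Bh <- matrix(0, 4, 4)
  Bh[2, 1] <- 0.7
  Bh[1, 4] <- 0.8
  Bh[3, 4] <- 0.6
  mh <- causalModel(Bh)
  covsH <- lapply(list(c(0, 0, 0, 0), c(2, 0.5, 1, 3), c(0.5, 3, 0.2, 5),
                       c(1, 1, 2, 8)),
                  function(v) populationCovariance(mh, v)[1:3, 1:3])
  avgH <- Reduce(`+`, covsH) / length(covsH)
  jdH <- jointDiagonalize(lapply(covsH, function(S) S - avgH))
  expect_gt(jdH$residual, 1e-4)

  expect_error(jointDiagonalize(diffs[1]), "length")
})

test_that("the scale/permutation ambiguity resolves through assignment", {
  m <- acyclicModel3()
  B <- connectivity(m)
  W <- diag(3) - B
  # permute rows and rescale: the construction must invert exactly
  perm <- c(3, 1, 2)
  Wmangled <- diag(c(2, -0.5, 7)) %*% W[perm, ]
  expect_lt(max(abs(resolveScalePermutation(Wmangled) - B)), 1e-12)

  # pure scaling: empty connectivity
  expect_equal(unname(resolveScalePermutation(2 * diag(3))),
               matrix(0, 3, 3))

  # an all-zero column admits no assignment
  Wbad <- diag(3)
  Wbad[, 2] <- 0
  expect_error(resolveScalePermutation(Wbad), "unresolvable")
})

test_that("connectivity estimation composes and respects preconditions", {
  m <- acyclicModel3()
  B <- connectivity(m)
  ivs <- threeEnvDesign()

  # two environments are not identifiable
  covs2 <- lapply(ivs[1:2], function(v) populationCovariance(m, v))
  expect_error(estimateBackshift(environmentSet(covs2)),
               "at least three environments")

  # population-level exactness, including intervention variances
  covs <- lapply(ivs, function(v) populationCovariance(m, v))
  est <- estimateBackshift(environmentSet(covs))
  expect_lt(max(abs(estimatedConnectivity(est) - B)), 1e-6)
  truthIv <- do.call(rbind, ivs)
  expect_lt(max(abs(interventionVariances(est) - truthIv)), 1e-6)

  # cyclic two-variable feedback model
  Bc <- matrix(c(0, 0.3, 0.4, 0), 2, 2)
  mc <- causalModel(Bc)
  covsC <- lapply(list(c(1, 2), c(2, 0.5), c(0.3, 3), c(0, 0)),
                  function(v) populationCovariance(mc, v))
  estC <- estimateBackshift(environmentSet(covsC))
  expect_lt(max(abs(estimatedConnectivity(estC) - Bc)), 1e-6)

  # finite-sample recovery on simulated cells
  tabs <- environmentTables(m, ivs, n = 10000, seed = 7)
  estS <- estimateBackshift(environmentCovariances(tabs))
  expect_lt(max(abs(estimatedConnectivity(estS) - B)), 0.05)
})

test_that("the estimator is equivariant to marker permutation and rescaling", {
  m <- acyclicModel3()
  B <- connectivity(m)
  covs <- lapply(threeEnvDesign(), function(v) populationCovariance(m, v))

  perm <- c(2, 3, 1)
  covsP <- lapply(covs, function(S) S[perm, perm])
  estP <- estimateBackshift(environmentSet(covsP))
  expect_lt(max(abs(estimatedConnectivity(estP) - B[perm, perm])), 1e-8)

  # rescaling marker i by s maps B[i, j] -> s B[i, j], B[j, i] -> B[j, i]/s
  s <- c(2, 0.5, 3)
  D <- diag(s)
  covsS <- lapply(covs, function(S) D %*% S %*% D)
  estS <- estimateBackshift(environmentSet(covsS))
  expect_lt(max(abs(estimatedConnectivity(estS) - D %*% B %*% solve(D))),
            1e-8)
})

test_that("the parametric bootstrap flags model violations", {
  m <- acyclicModel3()
  tabs <- environmentTables(m, c(threeEnvDesign(),
                                 list(c(1, 1, 4), c(3, 2, 0.3))),
                            n = 3000, seed = 5)
  env <- environmentCovariances(tabs)
  dg <- diagnoseModel(env, nBoot = 40, seed = 8)
  expect_true(dg$success)
  expect_lte(dg$ci[1], dg$ci[2])

  # correlated interventions within an environment break the diagonal
  # intervention-covariance assumption and must be detected
  B3 <- connectivity(m)
  M <- solve(diag(3) - B3)
  mkenv <- function(n, Sc, seed) {
    set.seed(seed)
    E <- matrix(rnorm(n * 3), n, 3)
    C <- matrix(rnorm(n * 3), n, 3) %*% chol(Sc + diag(1e-9, 3))
    X <- (E + C) %*% t(M)
    colnames(X) <- paste0("P", 1:3)
    X
  }
  Scor <- diag(c(3, 2, 1))
  Scor[1, 2] <- Scor[2, 1] <- 2.2
  viol <- list(mkenv(4000, diag(0, 3), 1), mkenv(4000, Scor, 2),
               mkenv(4000, diag(c(0.5, 3, 0.2)), 3),
               mkenv(4000, diag(c(4, 0.3, 1)), 4),
               mkenv(4000, diag(c(1, 1, 5)), 5))
  dgV <- tryCatch(diagnoseModel(environmentCovariances(viol),
                                nBoot = 40, seed = 9),
                  error = function(e) list(success = FALSE))
  expect_false(dgV$success)

  expect_error(diagnoseModel(env, nBoot = 0), "nBoot")
})

test_that("stability selection keeps true edges and controls false ones", {
  expect_equal(stabilityKeepCount(14, EV = 5, piThr = 0.75), 21L)
  expect_error(stabilityConfig(piThr = 0.4), "piThr")

  # strong two-edge model: exactly the true edges are stable
  B4 <- matrix(0, 4, 4)
  B4[2, 1] <- 0.8
  B4[4, 3] <- -0.7
  m4 <- causalModel(B4)
  ivs <- list(c(0, 0, 0, 0), c(4, 0.2, 1, 0.5), c(0.3, 4, 0.1, 2),
              c(1, 0.5, 4, 0.2))
  tabs <- environmentTables(m4, ivs, n = 4000, seed = 11)
  env <- environmentCovariances(tabs)
  sel <- stabilitySelect(env, tabs,
                         stabilityConfig(EV = 2, nSim = 50, piThr = 0.75,
                                         minSuccess = 38), seed = 12)
  # every true edge is stable; false stable edges stay within E(V)
  expect_true(all(c("P1 P2", "P3 P4") %in% paste(sel$from, sel$to)))
  expect_lte(nrow(sel) - 2L, 2L)
  expect_true(all(sel$selectionFrequency > 0.75))

  # pure noise: the stable set is small (expected false edges <= EV)
  m0 <- causalModel(matrix(0, 4, 4))
  tabs0 <- environmentTables(m0, ivs, n = 1000, seed = 13)
  sel0 <- stabilitySelect(environmentCovariances(tabs0), tabs0,
                          stabilityConfig(EV = 2, nSim = 50, piThr = 0.75,
                                          minSuccess = 38), seed = 14)
  expect_lte(nrow(sel0), 2)
})
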