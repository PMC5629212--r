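test_that("pooling attaches the activation indicator and filters small tables", {
  m <- chainModel3()
  ref <- simulateCondition(m, n = 100, seed = 1)
  act <- simulateCondition(m, activated = TRUE, n = 150, seed = 2)
  pooled <- poolActivation(ref, act)
  expect_equal(nrow(cellValues(pooled)), 250)
  expect_equal(mean(activationStatus(pooled)), 0.6)

  # tables below the cell-count floor are skipped with a message
  tiny <- simulateCondition(m, n = 15, seed = 3)
  expect_message(res <- poolActivation(tiny, act), "fewer than 20")
  expect_null(res)

  # marker orders are aligned by label before pooling
  shuffled <- cellTable(cellValues(act)[, c(3, 1, 2)],
                        activator = "act1")
  pooled2 <- poolActivation(ref, shuffled)
  expect_identical(colnames(cellValues(pooled2)), markerNames(m))
  expect_equal(unname(cellValues(pooled2)[101:250, ]),
               unname(cellValues(act)))

  # different panels cannot be pooled
  other <- cellTable(matrix(rnorm(80), 40, 2,
                            dimnames = list(NULL, c("Q1", "Q2"))))
  expect_error(poolActivation(ref, other), "marker mismatch")
})

test_that("the six-test trio rule identifies chains and stays silent otherwise", {
  # A -> S -> T: the S -> T chain pattern
  m <- chainModel3()
  pooled <- poolActivation(simulateCondition(m, n = 1000, seed = 10),
                           simulateCondition(m, activated = TRUE, n = 1000,
                                             seed = 11))
  out <- evaluateTrio(pooled, "P1", "P2")
  expect_s3_class(out, "TrioOutcome")
  expect_equal(out$label, "chain_S_to_T")
  expect_length(out$p, 6)
  # swapped arguments flag the reverse orientation of the same chain
  expect_equal(evaluateTrio(pooled, "P2", "P1")$label, "chain_T_to_S")

  # A -> S and A -> T with no S-T edge: independent model, no pattern
  B <- matrix(0, 3, 3)
  mi <- causalModel(B, a = c(1, 1, 0))
  pooledI <- poolActivation(simulateCondition(mi, n = 1500, seed = 12),
                            simulateCondition(mi, activated = TRUE, n = 1500,
                                              seed = 13))
  expect_equal(evaluateTrio(pooledI, "P1", "P2")$label, "no_pattern")

  # latent confounder S <- H -> T with A -> S: conditioning on the collider
  # path keeps A dependent on nothing it should not be; no chain emitted
  mc <- confounderModel3()
  pooledC <- poolActivation(simulateCondition(mc, n = 1500, seed = 14),
                            simulateCondition(mc, activated = TRUE, n = 1500,
                                              seed = 15))
  expect_false(evaluateTrio(pooledC, "P1", "P2")$label %in%
                 c("chain_S_to_T", "chain_T_to_S"))
})

test_that("replicate aggregation enforces the support threshold", {
  lab <- function(n, what) rep(what, n)
  out <- aggregateReplicates(c(lab(12, "chain_S_to_T"), lab(15, "no_pattern")))
  expect_equal(out$direction, "S_to_T")
  expect_equal(out$support, 12)
  expect_equal(out$total, 27)

  expect_null(aggregateReplicates(c(lab(9, "chain_S_to_T"),
                                    lab(18, "no_pattern"))))

  expect_message(
    conf <- aggregateReplicates(c(lab(10, "chain_S_to_T"),
                                  lab(10, "chain_T_to_S"),
                                  lab(7, "uncertain"))),
    "conflicting")
  expect_null(conf)

  expect_error(aggregateReplicates(list()), "empty")
})

test_that("trio discovery on a replicate study finds exactly the true chain", {
  b <- replicateStudy(chainModel3(), seed = 21)
  preds <- runCLCD(b)
  expect_equal(nrow(preds), 1L)
  expect_equal(preds$cause, "P1")
  expect_equal(preds$effect, "P2")
  expect_gte(preds$support, 10)
  expect_equal(preds$total, 27)

  # deterministic: identical rerun
  expect_identical(runCLCD(b), preds)

  # a pure-noise study emits nothing
  b0 <- replicateStudy(nullModel3(), seed = 22, n = 500)
  expect_equal(nrow(runCLCD(b0)), 0L)
})

test_that("predictions are ranked by context frequency with stable ties", {
  preds <- data.frame(
    cause = c("pErk", "pErk", "pErk", "pAkt", "pAkt", "pS6"),
    effect = c("pZap70", "pZap70", "pZap70", "pS6", "pS6", "pAkt"),
    activator = paste0("act", 1:6), subpopulation = "pop1")
  ranked <- rankPredictions(preds)
  expect_equal(ranked$cause[1], "pErk")
  expect_equal(ranked$frequency, c(3L, 2L, 1L))
  # equal frequencies break lexicographically
  tied <- rankPredictions(data.frame(cause = c("b", "a"), effect = c("x", "y")))
  expect_equal(tied$cause, c("a", "b"))
  expect_equal(nrow(rankPredictions(preds[0, ])), 0L)
})

test_that("threshold sensitivity is monotone and self-consistent", {
  b <- replicateStudy(chainModel3(), seed = 30, nReps = 15, n = 400)
  sens <- thresholdSensitivity(b, alphaGrid = c(1e-5, 1e-3),
                               betaGrid = c(0.15, 0.5),
                               minSupportGrid = c(6L),
                               defaultMinSupport = 6L)
  expect_equal(nrow(sens), 4L)
  defRow <- sens[sens$alpha == 1e-3 & sens$beta == 0.15, ]
  expect_equal(defRow$jaccard, 1)
  # stricter alpha cannot add predictions; raising the independence-
  # acceptance bar beta cannot add them either
  at <- function(a, bta) sens$nPredictions[sens$alpha == a & sens$beta == bta]
  expect_lte(at(1e-5, 0.15), at(1e-3, 0.15))
  expect_lte(at(1e-3, 0.5), at(1e-3, 0.15))
  expect_error(thresholdSensitivity(b, alphaGrid = 0.2, betaGrid = 0.15),
               "invalid grid")
})
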