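# Exact BGe scoring of candidate trio networks and consistency testing of
# predictions in independent data sets.

#' BGe prior hyperparameters
#'
#' Normal-Wishart prior for the Gaussian marginal likelihood: prior mean at
#' the sample mean (so the mean-shift term vanishes), precision weight
#' \code{alphaMu}, Wishart degrees of freedom \code{alphaW} (must exceed
#' \code{p - 1}), and identity prior scale matrix.
#'
#' @param alphaMu prior precision weight on the mean (default 1).
#' @param alphaW Wishart degrees of freedom (default p + 2 = 5 for trios).
#' @param p total number of variables jointly modeled (default 3: the
#'   activation indicator plus the two proteins).
#' @return list of class \code{"BGePrior"}.
#' @export
bgePrior <- function(alphaMu = 1, alphaW = 5, p = 3) {
  if (alphaW <= p - 1) stop("alphaW must exceed p - 1")
  structure(list(alphaMu = alphaMu, alphaW = alphaW, p = p),
            class = "BGePrior")
}

# log multivariate gamma
.lmvgamma <- function(a, l) {
  l * (l - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(l)) / 2))
}

# log marginal likelihood of the data restricted to the variable subset Y
# under the Normal-Wishart prior; the subset form keeps the score
# equivalent across Markov-equivalent structures
.bgeSubsetML <- function(Xc, N, prior, Y) {
  l <- length(Y)
  if (l == 0) return(0)
  p <- prior$p
  am <- prior$alphaMu
  aw <- prior$alphaW
  S <- crossprod(Xc[, Y, drop = FALSE])     # centered scatter
  TY <- diag(l)                             # identity prior scale, restricted
  R <- TY + S                               # prior mean = sample mean
  ldT <- 0                                  # log det identity
  ldR <- determinant(R, logarithm = TRUE)$modulus[1]
  -(N * l / 2) * log(pi) + (l / 2) * log(am / (N + am)) +
    .lmvgamma((N + aw - p + l) / 2, l) - .lmvgamma((aw - p + l) / 2, l) +
    ((aw - p + l) / 2) * ldT - ((N + aw - p + l) / 2) * ldR
}

# log marginal likelihoods of all subsets of {A, S, T}; names are sorted
# comma-joined variable sets
.bgeAllSubsets <- function(data, prior = bgePrior()) {
  X <- as.matrix(data[, c("A", "S", "T")])
  if (nrow(X) < 3) stop("at least 3 observations required for BGe scoring")
  if (any(apply(X, 2, sd) == 0))
    stop("singular data: constant column among A, S, T")
  Xc <- sweep(X, 2, colMeans(X))
  vars <- c("A", "S", "T")
  subsets <- unlist(lapply(0:3, function(k)
    combn(vars, k, simplify = FALSE)), recursive = FALSE)
  ml <- vapply(subsets, function(Y)
    .bgeSubsetML(Xc, nrow(X), prior, Y), numeric(1))
  names(ml) <- vapply(subsets, function(Y)
    paste(sort(Y), collapse = ","), character(1))
  ml
}

#' Enumerate candidate trio networks
#'
#' All DAGs over \{A, S, T\} in which the activation indicator A is
#' constrained to be a source (no incoming edges): presence of A->S times
#' presence of A->T times the S/T relation (none, S->T, T->S), i.e. twelve
#' networks, including the causal chain (A->S->T), the independent model
#' (A->S, A->T) and the full model.
#'
#' @return list of 3 x 3 0/1 adjacency matrices (entry [i, j] = 1 means
#'   i -> j) with dimnames A, S, T; names describe the edges; deterministic
#'   order.
#' @export
enumerateCandidateNetworks <- function() {
  vars <- c("A", "S", "T")
  nets <- list()
  for (aS in 0:1) for (aT in 0:1) for (st in c("none", "S->T", "T->S")) {
    adj <- matrix(0L, 3, 3, dimnames = list(vars, vars))
    if (aS) adj["A", "S"] <- 1L
    if (aT) adj["A", "T"] <- 1L
    if (st == "S->T") adj["S", "T"] <- 1L
    if (st == "T->S") adj["T", "S"] <- 1L
    edges <- c(if (aS) "A->S", if (aT) "A->T",
               if (st != "none") st)
    name <- if (length(edges)) paste(edges, collapse = ",") else "empty"
    nets[[name]] <- adj
  }
  nets
}

#' BGe log marginal likelihood of a trio network
#'
#' Decomposable score: the sum over nodes of local Normal-Wishart marginal
#' likelihood terms (family subset minus parent subset), equal across
#' Markov-equivalent DAGs. The binary activation indicator is scored as a
#' 0/1-valued continuous variable inside the Gaussian framework; see the
#' package vignette for the implications of that choice.
#'
#' @param data data.frame or matrix with columns \code{A} (0/1), \code{S},
#'   \code{T}.
#' @param network a 3 x 3 adjacency matrix from
#'   [enumerateCandidateNetworks()].
#' @param prior a [bgePrior()].
#' @return log marginal likelihood (numeric scalar).
#' @export
bgeScore <- function(data, network, prior = bgePrior()) {
  ml <- .bgeAllSubsets(data, prior)
  .bgeScoreFromSubsets(ml, network)
}

.bgeScoreFromSubsets <- function(ml, network) {
  vars <- c("A", "S", "T")
  total <- 0
  for (v in vars) {
    parents <- vars[network[, v] == 1L]
    fam <- paste(sort(c(parents, v)), collapse = ",")
    pa <- paste(sort(parents), collapse = ",")
    total <- total + ml[[fam]] - (if (nzchar(pa)) ml[[pa]] else 0)
  }
  unname(total)
}

#' Score all candidate networks on one table
#'
#' @param data data.frame/matrix with columns \code{A}, \code{S}, \code{T}.
#' @param prior a [bgePrior()].
#' @return named numeric vector of log scores over the twelve candidate
#'   networks.
#' @export
scoreCandidateNetworks <- function(data, prior = bgePrior()) {
  ml <- .bgeAllSubsets(data, prior)
  vapply(enumerateCandidateNetworks(), function(net)
    .bgeScoreFromSubsets(ml, net), numeric(1))
}

#' Classify a prediction against independent data
#'
#' Scores all twelve candidate trio networks on an independent table and
#' compares the best-scoring network with the predicted chain A->S->T:
#' \code{"consistent"} when the selected network is exactly the chain
#' (edges A->S and S->T only), \code{"conflicted"} when the selected
#' network contains the reversed edge T->S, otherwise \code{"other"}
#' (e.g. sparser networks when activation is not effective). Exact score
#' ties at the maximum are conservatively classified \code{"other"}.
#'
#' @param data independent table with columns \code{A} (0/1 activation),
#'   \code{S} (predicted cause), \code{T} (predicted effect).
#' @param prior a [bgePrior()].
#' @param tieTol relative tolerance for declaring a score tie.
#' @return list of class \code{"ConsistencyVerdict"}: \code{label},
#'   \code{best} (network name), \code{scores}.
#' @export
classifyPrediction <- function(data, prior = bgePrior(), tieTol = 1e-9) {
  scores <- scoreCandidateNetworks(data, prior)
  best <- which.max(scores)
  tied <- sum(scores >= scores[best] - tieTol * max(1, abs(scores[best])))
  bestName <- names(scores)[best]
  label <- if (tied > 1) {
    "other"
  } else if (bestName == "A->S,S->T") {
    "consistent"
  } else if (grepl("T->S", bestName, fixed = TRUE)) {
    "conflicted"
  } else {
    "other"
  }
  structure(list(label = label, best = bestName, scores = scores),
            class = "ConsistencyVerdict")
}

#' @export
print.ConsistencyVerdict <- function(x, ...) {
  cat(sprintf("ConsistencyVerdict: %s (best network: %s)\n", x$label, x$best))
  invisible(x)
}

# pooled A/S/T table for a (subpopulation, activator, S, T) context from an
# independent bundle: reference + activated cells over all dose-zero plates
.independentTrioTable <- function(bundle, subpopulation, activator, S, T,
                                  minCells = 20L) {
  tabs <- studyTables(bundle)
  pick <- function(act) {
    sel <- Filter(function(tab) {
      m <- tab@meta
      m$subpopulation == subpopulation && m$activator == act && m$dosage == 0L
    }, tabs)
    if (!length(sel)) return(NULL)
    do.call(rbind, lapply(sel, function(tab)
      tab@exprs[, c(S, T), drop = FALSE]))
  }
  ref <- pick("reference")
  act <- pick(activator)
  if (is.null(ref) || is.null(act) ||
      nrow(ref) < minCells || nrow(act) < minCells) return(NULL)
  data.frame(A = c(rep(0L, nrow(ref)), rep(1L, nrow(act))),
             S = c(ref[, S], act[, S]), T = c(ref[, T], act[, T]))
}

#' Consistency of predictions in an independent data set
#'
#' Classifies every prediction against the matching conditions of an
#' independent study, and compares the observed fraction of consistent
#' predictions with a stratified random baseline: \code{nRandom} random
#' prediction sets with the same number of predictions per (activator,
#' subpopulation) stratum, classified the same way. Significance is a
#' one-tailed one-sample t-test of the baseline consistency fractions
#' against the observed fraction.
#'
#' @param predictions data.frame with columns \code{cause}, \code{effect},
#'   \code{activator}, \code{subpopulation}.
#' @param bundle independent [StudyBundle-class].
#' @param nRandom number of random baseline sets (>= 2).
#' @param seed integer seed for the baseline draws.
#' @param prior a [bgePrior()].
#' @param minCells minimum pooled group size per condition.
#' @return list of class \code{"ConsistencyAnalysis"}: \code{rates}
#'   (consistent/conflicted/other fractions), \code{verdicts} (per
#'   prediction), \code{baseline} (per-iteration consistency fractions),
#'   \code{p.value}, \code{nScored}.
#' @export
consistencyAnalysis <- function(predictions, bundle, nRandom = 10L,
                                seed = NULL, prior = bgePrior(),
                                minCells = 20L) {
  if (!nrow(predictions)) stop("empty prediction set")
  if (nRandom < 2) stop("nRandom must be >= 2")
  markers <- colnames(studyTables(bundle)[[1]]@exprs)
  scoreSet <- function(preds) {
    labels <- vapply(seq_len(nrow(preds)), function(i) {
      tab <- .independentTrioTable(bundle, preds$subpopulation[i],
                                   preds$activator[i], preds$cause[i],
                                   preds$effect[i], minCells)
      if (is.null(tab)) return(NA_character_)
      tryCatch(classifyPrediction(tab, prior)$label,
               error = function(e) NA_character_)
    }, character(1))
    labels[!is.na(labels)]
  }
  observed <- scoreSet(predictions)
  if (!length(observed))
    stop("no prediction could be matched to a condition in the ",
         "independent study")
  rates <- c(consistent = mean(observed == "consistent"),
             conflicted = mean(observed == "conflicted"),
             other = mean(observed == "other"))
  strata <- split(seq_len(nrow(predictions)),
                  paste(predictions$activator, predictions$subpopulation,
                        sep = "|"))
  baseline <- .withSeed(seed, vapply(seq_len(nRandom), function(r) {
    rand <- predictions
    for (idx in strata) {
      k <- length(idx)
      pairs <- t(vapply(seq_len(k), function(i)
        sample(markers, 2), character(2)))
      rand$cause[idx] <- pairs[, 1]
      rand$effect[idx] <- pairs[, 2]
    }
    lab <- scoreSet(rand)
    if (!length(lab)) return(NA_real_)
    mean(lab == "consistent")
  }, numeric(1)))
  baseline <- baseline[!is.na(baseline)]
  p <- if (length(baseline) >= 2 && sd(baseline) > 0) {
    t.test(baseline, mu = rates[["consistent"]],
           alternative = "less")$p.value
  } else if (length(baseline)) {
    # degenerate baseline spread: boundary p-value
    if (mean(baseline) < rates[["consistent"]]) 0 else 1
  } else {
    NA_real_
  }
  structure(list(rates = rates, verdicts = observed, baseline = baseline,
                 p.value = p, nScored = length(observed)),
            class = "ConsistencyAnalysis")
}

#' @export
print.ConsistencyAnalysis <- function(x, ...) {
  cat(sprintf(
    "Consistency over %d scored predictions: %.1f%% consistent, %.1f%% conflicted, %.1f%% other\n",
    x$nScored, 100 * x$rates["consistent"], 100 * x$rates["conflicted"],
    100 * x$rates["other"]))
  cat(sprintf("  random baseline %.1f%%, one-tailed p = %.3g\n",
              100 * mean(x$baseline), x$p.value))
  invisible(x)
}
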