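# Connectivity estimation from shift-intervention environments by joint
# diagonalization of covariance differences.
#
# Model: x^e = B x^e + c^e + eps, with Cov(c^e) diagonal and B, Cov(eps)
# invariant across environments, so
#   (I - B) Sigma_x^e (I - B)^T = Sigma_eps + Sigma_c^e.
# Differencing covariances across environments removes the invariant
# Sigma_eps and leaves matrices that (I - B) diagonalizes simultaneously.

#' Sample covariances per environment
#'
#' Computes the unbiased sample covariance of each environment's table and
#' packages them with sample sizes. Each environment needs at least
#' \code{p + 1} cells and no constant marker.
#'
#' @param tables list of [CellTable-class] objects or cells x markers
#'   matrices over a common marker panel, one per environment.
#' @return An object of class \code{"EnvironmentSet"}: list with
#'   \code{covariances}, \code{n}, \code{markers}, \code{labels}.
#' @export
environmentCovariances <- function(tables) {
  mats <- lapply(tables, function(tab)
    if (is(tab, "CellTable")) tab@exprs else as.matrix(tab))
  markers <- colnames(mats[[1]])
  p <- ncol(mats[[1]])
  covs <- lapply(seq_along(mats), function(e) {
    X <- mats[[e]]
    if (!identical(colnames(X), markers))
      stop("environment ", e, " has a different marker panel")
    if (nrow(X) < p + 1)
      stop("environment ", e, " has n = ", nrow(X),
           " cells; at least p + 1 = ", p + 1, " are required")
    v <- apply(X, 2, var)
    if (any(v == 0))
      stop("constant marker '", markers[which(v == 0)[1]],
           "' in environment ", e)
    cov(X)
  })
  labels <- names(tables) %||% paste0("env", seq_along(tables))
  structure(list(covariances = covs,
                 n = vapply(mats, nrow, 0L),
                 markers = markers, labels = labels),
            class = "EnvironmentSet")
}

#' Assemble an EnvironmentSet from known covariances
#'
#' Used for population-level analyses where exact covariance matrices are
#' available in closed form.
#'
#' @param covariances list of p x p covariance matrices.
#' @param n sample size(s) to record (recycled).
#' @return An \code{"EnvironmentSet"}.
#' @export
environmentSet <- function(covariances, n = Inf) {
  p <- ncol(covariances[[1]])
  markers <- colnames(covariances[[1]]) %||% paste0("P", seq_len(p))
  structure(list(covariances = lapply(covariances, unname),
                 n = rep(n, length.out = length(covariances)),
                 markers = markers,
                 labels = names(covariances) %||%
                   paste0("env", seq_along(covariances))),
            class = "EnvironmentSet")
}

#' @export
print.EnvironmentSet <- function(x, ...) {
  cat(sprintf("EnvironmentSet: %d environments x %d markers (n: %s)\n",
              length(x$covariances), length(x$markers),
              paste(x$n, collapse = ", ")))
  invisible(x)
}

# sum of squared off-diagonal entries of W D_k W^T over k, normalized by
# the total squared norm (scale-free residual)
.jointResidual <- function(W, diffs) {
  off <- 0
  tot <- 0
  for (D in diffs) {
    C <- W %*% D %*% t(W)
    off <- off + sum(C^2) - sum(diag(C)^2)
    tot <- tot + sum(C^2)
  }
  if (tot == 0) 0 else off / tot
}

#' Joint diagonalization of symmetric matrices
#'
#' Finds a (non-orthogonal) matrix W that simultaneously diagonalizes a set
#' of symmetric matrices, minimizing the summed squared off-diagonal
#' entries of \eqn{W \Delta_k W^T}. Uses a Frobenius-norm multiplicative
#' update scheme: at each sweep the first-order optimal zero-diagonal
#' update U is obtained per index pair from a 2x2 linear system in the
#' current diagonals, and \eqn{W \leftarrow (I + U) W} with a step-size
#' guard and row renormalization. Deterministic: initialized at the
#' identity.
#'
#' @param diffs list of at least two symmetric p x p matrices (covariance
#'   differences).
#' @param tol convergence tolerance on the update size and residual change.
#' @param maxIter maximum sweeps.
#' @param theta cap on the max-norm of the update per sweep.
#' @return list with \code{W} (rows scaled to unit norm), \code{residual}
#'   (scale-normalized off-diagonal sum), \code{iterations},
#'   \code{converged}.
#' @export
jointDiagonalize <- function(diffs, tol = 1e-10, maxIter = 1000L,
                             theta = 0.9) {
  stopifnot(length(diffs) >= 2)
  p <- nrow(diffs[[1]])
  diffs <- lapply(diffs, function(D) unname((D + t(D)) / 2))
  W <- diag(p)
  resid <- .jointResidual(W, diffs)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxIter)) {
    Cs <- lapply(diffs, function(D) W %*% D %*% t(W))
    ds <- lapply(Cs, diag)
    # per-pair 2x2 normal equations, all pairs at once:
    #   [ v[j]  M[i,j] ] [U_ij]   [P[i,j]]
    #   [ M[i,j]  v[i] ] [U_ji] = -[Q[i,j]]
    # with v = sum_k d_k^2, M = sum_k d_k d_k^T,
    # P[i,j] = sum_k E_k[i,j] d_k[j], Q[i,j] = sum_k d_k[i] E_k[i,j]
    v <- Reduce(`+`, lapply(ds, function(d) d^2))
    M <- Reduce(`+`, lapply(ds, function(d) d %o% d))
    P <- Reduce(`+`, Map(function(C, d) {
      E <- C - diag(diag(C))
      E * rep(d, each = p)          # E[i,j] * d[j]
    }, Cs, ds))
    Q <- Reduce(`+`, Map(function(C, d) {
      E <- C - diag(diag(C))
      E * d                          # E[i,j] * d[i]
    }, Cs, ds))
    Vj <- matrix(v, p, p, byrow = TRUE)  # v[j] at (i,j)
    Vi <- matrix(v, p, p)                # v[i] at (i,j)
    det2 <- Vj * Vi - M^2
    # the elementwise formula at (i,j) solves the pair system for U[i,j];
    # by the symmetry E_k[i,j] = E_k[j,i] it simultaneously yields U[j,i]
    # when evaluated at (j,i), so one pass fills the whole matrix
    U <- matrix(0, p, p)
    ok <- det2 > .Machine$double.eps * pmax(Vj * Vi, 1)
    U[ok] <- ((-P * Vi + Q * M) / det2)[ok]
    diag(U) <- 0
    # step-size guard
    mx <- max(abs(U))
    if (mx > theta) U <- U * (theta / mx)
    # backtracking keeps the sweep monotone: the linearized update can
    # overshoot when the matrices are far from jointly diagonalizable
    newResid <- resid
    for (bt in 1:8) {
      Wnew <- (diag(p) + U) %*% W
      Wnew <- Wnew / sqrt(rowSums(Wnew^2))
      newResid <- .jointResidual(Wnew, diffs)
      if (newResid <= resid || resid == 0) break
      U <- U / 2
    }
    if (newResid > resid) {
      # no descent direction left: local minimum
      converged <- TRUE
      break
    }
    W <- Wnew
    if (max(abs(U)) < tol || abs(resid - newResid) < tol * max(resid, 1e-300)) {
      resid <- newResid
      converged <- TRUE
      break
    }
    resid <- newResid
  }
  if (!converged && resid > tol)
    stop(sprintf(
      "joint diagonalization did not converge in %d iterations (residual %.3g)",
      maxIter, resid))
  list(W = W, residual = resid, iterations = iter, converged = converged)
}

#' Resolve the scale/permutation ambiguity of a diagonalizer
#'
#' A joint diagonalizer is only determined up to row permutation and
#' scaling. The permutation is fixed by a linear sum assignment maximizing
#' \eqn{\sum_i \log |W_{\sigma(i), i}|} (solved as a maximum-weight
#' bipartite matching); each row is then rescaled so its diagonal entry is
#' one, and \eqn{\hat B = I - W}.
#'
#' @param W invertible p x p diagonalizer.
#' @param labels optional marker names for the result.
#' @return p x p matrix \code{Bhat} with exactly zero diagonal.
#' @export
resolveScalePermutation <- function(W, labels = NULL) {
  p <- nrow(W)
  A <- abs(W)
  lw <- suppressWarnings(log(A))
  finite <- is.finite(lw)
  if (any(colSums(finite) == 0) || any(rowSums(finite) == 0))
    stop("unresolvable permutation: W has an all-zero row or column")
  edges <- which(finite, arr.ind = TRUE)
  # shift weights so every perfect matching dominates any partial one
  shift <- p * (max(lw[finite]) - min(lw[finite])) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, p), rep(TRUE, p)),
    edges = as.vector(t(cbind(edges[, 1], p + edges[, 2]))))
  igraph::E(g)$weight <- lw[edges] + shift
  m <- igraph::max_bipartite_match(g)
  matched <- m$matching[seq_len(p)] - p  # row i -> column matched[i]
  if (anyNA(matched) || length(unique(matched)) != p)
    stop("unresolvable permutation: no perfect assignment exists")
  perm <- order(matched)  # row perm[j] lands on row j
  Wp <- W[perm, , drop = FALSE]
  d <- diag(Wp)
  if (any(abs(d) < .Machine$double.eps))
    stop("unresolvable permutation: zero diagonal after assignment")
  Bhat <- diag(p) - Wp / d
  diag(Bhat) <- 0
  if (!is.null(labels)) dimnames(Bhat) <- list(labels, labels)
  Bhat
}

#' Estimate the connectivity matrix from shift-intervention environments
#'
#' Differences each environment's covariance against the pooled average
#' (which removes the environment-invariant noise covariance), jointly
#' diagonalizes the differences, resolves the scale/permutation ambiguity,
#' and estimates per-environment intervention variances as the diagonal of
#' \eqn{(I-\hat B)\Sigma_x^e(I-\hat B)^T} minus its environment-wise
#' minimum (clipped at zero). At least three environments are required for
#' identifiability.
#'
#' @param envSet an \code{"EnvironmentSet"}.
#' @param differencing \code{"pooled"} (default: each covariance minus the
#'   average) or \code{"pairwise"} (consecutive differences).
#' @param tol,maxIter passed to [jointDiagonalize()].
#' @return A [ConnectivityEstimate-class].
#' @export
estimateBackshift <- function(envSet, differencing = c("pooled", "pairwise"),
                              tol = 1e-10, maxIter = 1000L) {
  differencing <- match.arg(differencing)
  covs <- envSet$covariances
  if (length(covs) < 3)
    stop("at least three environments are required for identifiability; got ",
         length(covs))
  if (differencing == "pooled") {
    avg <- Reduce(`+`, covs) / length(covs)
    diffs <- lapply(covs, function(S) S - avg)
  } else {
    diffs <- Map(function(S1, S2) S1 - S2, covs[-1], covs[-length(covs)])
  }
  jd <- jointDiagonalize(diffs, tol = tol, maxIter = maxIter)
  Bhat <- resolveScalePermutation(jd$W, labels = envSet$markers)
  ImB <- diag(nrow(Bhat)) - Bhat
  raw <- t(vapply(covs, function(S) diag(ImB %*% S %*% t(ImB)),
                  numeric(nrow(Bhat))))
  iv <- sweep(raw, 2, apply(raw, 2, min))
  clipped <- sum(iv < 0)
  if (clipped) message("clipped ", clipped,
                       " negative intervention-variance estimate(s) to zero")
  iv[iv < 0] <- 0
  colnames(iv) <- envSet$markers
  rownames(iv) <- envSet$labels
  new("ConnectivityEstimate", Bhat = Bhat, interventionVariances = iv,
      residual = jd$residual, labels = envSet$markers)
}

# model-implied environment covariances from an estimate: Sigma_eps is
# recomposed from the rotated covariances (off-diagonals averaged, diagonal
# = environment minimum), eigenvalue-clipped to PSD
.impliedModel <- function(envSet, estimate) {
  Bhat <- estimate@Bhat
  p <- nrow(Bhat)
  ImB <- diag(p) - Bhat
  Ts <- lapply(envSet$covariances, function(S) ImB %*% S %*% t(ImB))
  offAvg <- Reduce(`+`, Ts) / length(Ts)
  SigmaEps <- offAvg - diag(diag(offAvg)) +
    diag(apply(vapply(Ts, diag, numeric(p)), 1, min), p)
  ee <- eigen((SigmaEps + t(SigmaEps)) / 2, symmetric = TRUE)
  SigmaEps <- ee$vectors %*% (pmax(ee$values, 1e-8) * t(ee$vectors))
  list(Bhat = Bhat, SigmaEps = SigmaEps,
       interventionVariances = estimate@interventionVariances)
}

#' Parametric-bootstrap diagnostic of the diagonalization
#'
#' Model violations (hidden intervention targets, correlated interventions,
#' fat-hand effects) leave the covariance differences non-diagonalizable.
#' This diagnostic refits the estimator on \code{nBoot} datasets simulated
#' from the fitted model (estimated connectivity, noise covariance and
#' intervention variances) and flags success when the observed residual
#' does not exceed the bootstrap residual distribution's upper quantile.
#'
#' @param envSet an \code{"EnvironmentSet"} with finite sample sizes.
#' @param nBoot number of bootstrap datasets (>= 1).
#' @param seed integer seed.
#' @param level upper quantile defining success (default 0.95).
#' @return list of class \code{"DiagnosticsReport"}: \code{residual},
#'   \code{ci} (bootstrap 2.5/97.5 percentiles), \code{threshold},
#'   \code{success}, \code{nBoot}, \code{nFailed}.
#' @export
diagnoseModel <- function(envSet, nBoot = 100L, seed = NULL, level = 0.95) {
  if (nBoot < 1) stop("nBoot must be >= 1")
  estimate <- estimateBackshift(envSet)
  fitted <- .impliedModel(envSet, estimate)
  p <- nrow(fitted$Bhat)
  M <- solve(diag(p) - fitted$Bhat)
  ns <- envSet$n
  if (any(!is.finite(ns)))
    stop("bootstrap requires finite per-environment sample sizes")
  .withSeed(seed, {
    boot <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
      tabs <- lapply(seq_along(ns), function(e) {
        E <- .rmvnorm(ns[e], fitted$SigmaEps)
        iv <- fitted$interventionVariances[e, ]
        C <- matrix(rnorm(ns[e] * p), ns[e], p) *
          rep(sqrt(iv), each = ns[e])
        X <- (E + C) %*% t(M)
        colnames(X) <- envSet$markers
        X
      })
      boot[b] <- tryCatch(
        diagonalizationResidual(
          estimateBackshift(environmentCovariances(tabs))),
        error = function(e) NA_real_)
    }
    nFailed <- sum(is.na(boot))
    if (nFailed == nBoot) stop("all bootstrap refits failed")
    thr <- quantile(boot, level, na.rm = TRUE, names = FALSE)
    structure(list(
      residual = diagonalizationResidual(estimate),
      ci = quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
      threshold = thr,
      success = diagonalizationResidual(estimate) <= thr,
      nBoot = nBoot, nFailed = nFailed), class = "DiagnosticsReport")
  })
}

#' @export
print.DiagnosticsReport <- function(x, ...) {
  cat(sprintf(
    "Diagonalization diagnostic: residual %.3g vs bootstrap 95%% %.3g -> %s\n",
    x$residual, x$threshold, if (x$success) "success" else "FAILURE"))
  if (x$nFailed) cat("  (", x$nFailed, "of", x$nBoot, "refits failed )\n")
  invisible(x)
}

#' Stability-selection configuration
#'
#' @param EV expected number of falsely selected edges (default 5).
#' @param nSim number of subsample refits (default 100).
#' @param piThr selection-frequency threshold in (0.5, 1) (default 0.75).
#' @param minSuccess minimum successful diagonalizations out of \code{nSim}
#'   for the result to be kept (default 75).
#' @return list of class \code{"StabilityConfig"}.
#' @export
stabilityConfig <- function(EV = 5, nSim = 100L, piThr = 0.75,
                            minSuccess = 75L) {
  if (!(piThr > 0.5 && piThr < 1)) stop("piThr must be in (0.5, 1)")
  if (nSim < 1) stop("nSim must be >= 1")
  structure(list(EV = EV, nSim = as.integer(nSim), piThr = piThr,
                 minSuccess = as.integer(minSuccess)),
            class = "StabilityConfig")
}

#' Per-refit keep count for stability selection
#'
#' Number of largest-coefficient edges kept in each subsample refit,
#' derived from the expected-false-selections bound
#' \eqn{E(V) \le q^2 / ((2\pi_{thr}-1)\,p(p-1))}:
#' \eqn{q = \lfloor\sqrt{E(V)(2\pi_{thr}-1)p(p-1)}\rfloor}.
#'
#' @param p number of markers.
#' @param EV expected false selections.
#' @param piThr selection-frequency threshold.
#' @return integer keep count.
#' @export
stabilityKeepCount <- function(p, EV = 5, piThr = 0.75) {
  as.integer(floor(sqrt(EV * (2 * piThr - 1) * p * (p - 1))))
}

#' Stable edge set by subsample refitting
#'
#' Refits the connectivity estimator on \code{nSim} random half-subsamples
#' of every environment, keeps the q largest-magnitude coefficients per
#' refit, and reports the edges selected in more than \code{piThr * nSim}
#' refits. The whole result is discarded with an error when fewer than
#' \code{minSuccess} refits achieve a successful diagonalization, since the
#' model assumptions are then considered violated. An empty stable set is a
#' valid result.
#'
#' @param envSet an \code{"EnvironmentSet"} built from tables (finite n).
#' @param tables list of per-environment [CellTable-class] or matrices
#'   (needed for subsampling); if \code{NULL}, taken from
#'   \code{attr(envSet, "tables")}.
#' @param config a [stabilityConfig()].
#' @param seed integer seed.
#' @return data.frame of class \code{"StableEdges"} with columns
#'   \code{from}, \code{to}, \code{coefficient} (full-data point estimate),
#'   \code{selectionFrequency}; attribute \code{nSuccess}.
#' @export
stabilitySelect <- function(envSet, tables, config = stabilityConfig(),
                            seed = NULL) {
  stopifnot(inherits(config, "StabilityConfig"))
  mats <- lapply(tables, function(tab)
    if (is(tab, "CellTable")) tab@exprs else as.matrix(tab))
  p <- length(envSet$markers)
  q <- stabilityKeepCount(p, config$EV, config$piThr)
  offIdx <- which(row(matrix(0, p, p)) != col(matrix(0, p, p)))
  counts <- numeric(p * p)
  nSuccess <- 0L
  .withSeed(seed, {
    for (s in seq_len(config$nSim)) {
      sub <- lapply(mats, function(X) {
        X[sample(nrow(X), floor(nrow(X) / 2)), , drop = FALSE]
      })
      fit <- tryCatch(
        estimateBackshift(environmentCovariances(sub)),
        error = function(e) NULL)
      if (is.null(fit)) next
      nSuccess <- nSuccess + 1L
      ab <- abs(fit@Bhat)[offIdx]
      keep <- offIdx[order(ab, decreasing = TRUE)[seq_len(min(q, length(ab)))]]
      counts[keep] <- counts[keep] + 1
    }
  })
  if (nSuccess < config$minSuccess)
    stop("model violated: joint diagonalization succeeded in only ",
         nSuccess, " of ", config$nSim, " subsample refits (minimum ",
         config$minSuccess, ")")
  freq <- counts / nSuccess
  stable <- which(freq > config$piThr)
  pointFit <- estimateBackshift(envSet)
  rowi <- ((stable - 1) %% p) + 1
  colj <- ((stable - 1) %/% p) + 1
  res <- data.frame(
    from = envSet$markers[colj], to = envSet$markers[rowi],
    coefficient = pointFit@Bhat[stable],
    selectionFrequency = freq[stable],
    stringsAsFactors = FALSE)
  res <- res[order(-res$selectionFrequency, res$from, res$to), , drop = FALSE]
  attr(res, "nSuccess") <- nSuccess
  attr(res, "q") <- q
  class(res) <- c("StableEdges", "data.frame")
  res
}
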