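# Conditional-independence tests and the dual-threshold decision rule.

#' Dual decision thresholds
#'
#' Independence is rejected below \code{alpha} and accepted above
#' \code{beta}; p-values in between are inconclusive. The defaults are the
#' conservative pair used throughout the trio analysis: 0.001 for rejecting
#' and 0.15 for accepting independence.
#'
#' @param alpha reject-independence threshold.
#' @param beta accept-independence threshold.
#' @return A list of class \code{"DecisionThresholds"}.
#' @export
ciThresholds <- function(alpha = 0.001, beta = 0.15) {
  if (!(alpha > 0 && alpha < beta && beta < 1))
    stop("thresholds must satisfy 0 < alpha < beta < 1")
  structure(list(alpha = alpha, beta = beta), class = "DecisionThresholds")
}

.newCITestResult <- function(test, statistic, p, n, conditioning = character(0)) {
  structure(list(test = test, statistic = unname(statistic),
                 p.value = unname(p), n = n,
                 conditioning = conditioning),
            class = "CITestResult")
}

#' @export
print.CITestResult <- function(x, ...) {
  cond <- if (length(x$conditioning))
    paste0(" | ", paste(x$conditioning, collapse = ", ")) else ""
  cat(sprintf("%s%s: statistic = %.4g, p = %.4g (n = %d)\n",
              x$test, cond, x$statistic, x$p.value, x$n))
  invisible(x)
}

#' Two-sample location test of a marker against the activation indicator
#'
#' Welch's unequal-variance t-test of the marker values between the two
#' activation groups; tests marginal (in)dependence between a continuous
#' marker and the binary activation indicator.
#'
#' @param x numeric marker values.
#' @param a binary 0/1 activation indicator (both groups must have at least
#'   two observations and non-zero variance).
#' @return A \code{CITestResult} with the two-sided p-value.
#' @export
tTestMarginal <- function(x, a) {
  stopifnot(length(x) == length(a))
  a <- as.integer(a)
  if (length(unique(a)) < 2)
    stop("degenerate grouping: activation indicator is constant")
  x0 <- x[a == 0L]
  x1 <- x[a == 1L]
  if (length(x0) < 2 || length(x1) < 2)
    stop("degenerate grouping: each group needs >= 2 observations")
  v0 <- var(x0)
  v1 <- var(x1)
  if (v0 == 0 && v1 == 0) {
    if (mean(x0) == mean(x1))
      return(.newCITestResult("welch-t", 0, 1, length(x)))
    stop("zero within-group variance with distinct means")
  }
  if (v0 == 0 || v1 == 0) stop("zero within-group variance")
  n0 <- length(x0)
  n1 <- length(x1)
  se2 <- v0 / n0 + v1 / n1
  stat <- (mean(x1) - mean(x0)) / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1))
  p <- 2 * pt(-abs(stat), df)
  .newCITestResult("welch-t", stat, p, length(x))
}

# partial correlation of x and y given the columns of z, by residualizing
# both on (1, z); a rank-deficient conditioning set is an error
.partialCor <- function(x, y, z = NULL) {
  Z <- cbind(rep(1, length(x)), z)
  qz <- qr(Z)
  if (qz$rank < ncol(Z))
    stop("collinear conditioning set")
  rx <- qr.resid(qz, x)
  ry <- qr.resid(qz, y)
  sx <- sqrt(sum(rx^2))
  sy <- sqrt(sum(ry^2))
  if (sx == 0 || sy == 0)
    stop("degenerate input: a variable is constant given the conditioning set")
  max(-1, min(1, sum(rx * ry) / (sx * sy)))
}

#' Fisher z-test of (conditional) independence of two markers
#'
#' Tests zero partial correlation of \code{x} and \code{y} given the
#' conditioning columns \code{z} (which may include a 0/1-coded activation
#' indicator). The statistic is \eqn{\mathrm{atanh}(r)\sqrt{n - |z| - 3}}
#' referred to a standard normal.
#'
#' @param x,y numeric marker values.
#' @param z optional conditioning vector or matrix.
#' @return A \code{CITestResult}.
#' @export
fisherZTest <- function(x, y, z = NULL) {
  if (!is.null(z)) z <- as.matrix(z)
  nz <- if (is.null(z)) 0L else ncol(z)
  n <- length(x)
  stopifnot(length(y) == n, is.null(z) || nrow(z) == n)
  if (n - nz - 3 < 1) stop("too few observations for the Fisher z-test")
  r <- .partialCor(x, y, z)
  condNames <- if (nz) paste0("z", seq_len(nz)) else character(0)
  if (abs(r) >= 1) {
    warning("perfect (partial) correlation; p-value is 0")
    return(.newCITestResult("fisher-z", sign(r) * Inf, 0, n, condNames))
  }
  stat <- atanh(r) * sqrt(n - nz - 3)
  p <- 2 * pnorm(-abs(stat))
  .newCITestResult("fisher-z", stat, p, n, condNames)
}

# binomial log-likelihood of a glm.fit result
.binomLogLik <- function(fit, a) {
  mu <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
  sum(a * log(mu) + (1 - a) * log(1 - mu))
}

#' Logistic likelihood-ratio test of activation against a marker
#'
#' Tests conditional (in)dependence of the binary activation indicator
#' \code{a} and a marker \code{x} given conditioning markers \code{z}, by a
#' likelihood-ratio comparison of the logistic regressions
#' \code{a ~ z + x} versus \code{a ~ z}, referred to a chi-square with one
#' degree of freedom. A Wald variant is available via \code{type}.
#'
#' @param a binary 0/1 vector (both classes present).
#' @param x numeric marker tested for inclusion.
#' @param z optional conditioning vector or matrix.
#' @param type \code{"lr"} (default) or \code{"wald"}.
#' @param allowSeparation if \code{TRUE}, perfect separation returns p = 0
#'   instead of an error.
#' @return A \code{CITestResult}.
#' @export
logisticLRTest <- function(a, x, z = NULL, type = c("lr", "wald"),
                           allowSeparation = FALSE) {
  type <- match.arg(type)
  a <- as.integer(a)
  n <- length(a)
  stopifnot(length(x) == n)
  if (length(unique(a)) < 2) stop("degenerate grouping: both classes of a required")
  if (!is.null(z)) {
    z <- as.matrix(z)
    stopifnot(nrow(z) == n)
  }
  X0 <- cbind(`(Intercept)` = rep(1, n), z)
  X1 <- cbind(X0, x = x)
  fit1 <- suppressWarnings(stats::glm.fit(X1, a, family = stats::binomial()))
  sep <- any(fit1$fitted.values < 1e-8 | fit1$fitted.values > 1 - 1e-8)
  if (sep && !allowSeparation)
    stop("perfect separation in the logistic fit; rerun with ",
         "allowSeparation = TRUE to report p = 0")
  if (!fit1$converged && !sep) stop("logistic fit did not converge")
  condNames <- if (is.null(z)) character(0) else paste0("z", seq_len(ncol(z)))
  if (var(x) == 0)
    return(.newCITestResult(paste0("logistic-", type), 0, 1, n, condNames))
  if (type == "lr") {
    fit0 <- suppressWarnings(stats::glm.fit(X0, a, family = stats::binomial()))
    if (!fit0$converged) stop("logistic null fit did not converge")
    stat <- 2 * (.binomLogLik(fit1, a) - .binomLogLik(fit0, a))
    stat <- max(stat, 0)
    p <- if (sep) 0 else pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    # Wald: coefficient / SE from the final IRLS weights
    W <- fit1$weights
    XtWX <- crossprod(X1 * sqrt(W))
    V <- tryCatch(solve(XtWX), error = function(e)
      stop("singular information matrix in the logistic fit"))
    k <- ncol(X1)
    stat <- (fit1$coefficients[k] / sqrt(V[k, k]))^2
    p <- if (sep) 0 else pchisq(stat, df = 1, lower.tail = FALSE)
  }
  .newCITestResult(paste0("logistic-", type), stat, p, n, condNames)
}

#' Dual-threshold decision on a p-value
#'
#' @param p p-value in [0, 1].
#' @param thresholds a [ciThresholds()] object.
#' @return \code{"dependent"} when \code{p < alpha}, \code{"independent"}
#'   when \code{p > beta}, otherwise \code{"uncertain"}.
#' @export
ciDecide <- function(p, thresholds = ciThresholds()) {
  stopifnot(inherits(thresholds, "DecisionThresholds"),
            p >= 0, p <= 1)
  if (p < thresholds$alpha) "dependent"
  else if (p > thresholds$beta) "independent"
  else "uncertain"
}
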