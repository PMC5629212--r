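# Conservative local causal discovery over activator/protein trios.

#' Pool a reference and an activated condition
#'
#' Stacks the unstimulated reference table and an activated table into one
#' pooled table carrying a binary activation column (0 = reference, 1 =
#' activated). Markers are aligned by label. Conditions with fewer than
#' \code{minCells} cells are not used: the pooling returns \code{NULL} with
#' a message, and the caller records the skip.
#'
#' @param reference,activated [CellTable-class] objects over the same
#'   marker panel.
#' @param minCells minimum cells per input table (default 20).
#' @return A pooled [CellTable-class], or \code{NULL} when an input is
#'   undersized.
#' @export
poolActivation <- function(reference, activated, minCells = 20L) {
  mr <- colnames(reference@exprs)
  ma <- colnames(activated@exprs)
  if (!setequal(mr, ma))
    stop("marker mismatch between reference and activated tables")
  if (nrow(reference@exprs) < minCells || nrow(activated@exprs) < minCells) {
    message(sprintf(
      "skipping condition [%s | %s | %s]: fewer than %d cells (ref %d, act %d)",
      activated@meta$subpopulation, activated@meta$activator,
      activated@meta$inhibitor, minCells, nrow(reference@exprs),
      nrow(activated@exprs)))
    return(NULL)
  }
  X <- rbind(reference@exprs[, mr, drop = FALSE],
             activated@exprs[, mr, drop = FALSE])
  act <- c(rep(0L, nrow(reference@exprs)), rep(1L, nrow(activated@exprs)))
  cellTable(X, subpopulation = activated@meta$subpopulation,
            activator = activated@meta$activator,
            inhibitor = activated@meta$inhibitor,
            dosage = activated@meta$dosage,
            replicate = activated@meta$replicate,
            activation = act)
}

# the six p-values of the trio pattern on a pooled table; NA on degenerate
# failures, with the reason attached
.trioPvalues <- function(pooled, S, T) {
  a <- pooled@activation
  xS <- pooled@exprs[, S]
  xT <- pooled@exprs[, T]
  safe <- function(expr) tryCatch(expr$p.value, error = function(e) {
    structure(NA_real_, reason = conditionMessage(e))
  })
  c(SA    = safe(tTestMarginal(xS, a)),
    TA    = safe(tTestMarginal(xT, a)),
    ST    = safe(fisherZTest(xS, xT)),
    ST.A  = safe(fisherZTest(xS, xT, z = a)),
    SA.T  = safe(logisticLRTest(a, xS, z = xT, allowSeparation = TRUE)),
    TA.S  = safe(logisticLRTest(a, xT, z = xS, allowSeparation = TRUE)))
}

# decision rule on the six p-values: which chain pattern (if any) holds
.trioLabel <- function(p, thresholds) {
  alpha <- thresholds$alpha
  beta <- thresholds$beta
  if (anyNA(p)) return("uncertain")
  dep <- p < alpha
  ind <- p > beta
  sToT <- dep[["SA"]] && dep[["TA"]] && dep[["ST"]] && dep[["ST.A"]] &&
    dep[["SA.T"]] && ind[["TA.S"]]
  tToS <- dep[["SA"]] && dep[["TA"]] && dep[["ST"]] && dep[["ST.A"]] &&
    dep[["TA.S"]] && ind[["SA.T"]]
  if (sToT && tToS) return("uncertain")
  if (sToT) return("chain_S_to_T")
  if (tToS) return("chain_T_to_S")
  if (any(!dep & !ind)) return("uncertain")
  "no_pattern"
}

#' Evaluate one activator/protein trio
#'
#' Computes the six conditional (in)dependence p-values of the trio
#' (activation A; candidate cause S; candidate effect T) on a pooled table:
#' S-A and T-A (Welch t), S-T and S-T|A (Fisher z), S-A|T and T-A|S
#' (logistic likelihood ratio). The chain S->T is called when S-A, T-A,
#' S-T, S-T|A and S-A|T are all rejected below \code{alpha} while T-A|S is
#' accepted above \code{beta}; symmetrically for T->S. Any required
#' dependence landing between the thresholds, a degenerate test, or both
#' directions holding at once yields \code{"uncertain"}; otherwise the
#' pattern is absent (\code{"no_pattern"}).
#'
#' @param pooled a pooled [CellTable-class] with activation column.
#' @param S,T marker names (distinct, present in the table).
#' @param thresholds a [ciThresholds()] object.
#' @return A list of class \code{"TrioOutcome"} with elements \code{label}
#'   and \code{p} (the six named p-values).
#' @export
evaluateTrio <- function(pooled, S, T, thresholds = ciThresholds()) {
  stopifnot(S != T, all(c(S, T) %in% colnames(pooled@exprs)),
            length(pooled@activation) == nrow(pooled@exprs))
  p <- .trioPvalues(pooled, S, T)
  structure(list(label = .trioLabel(p, thresholds), p = p, S = S, T = T),
            class = "TrioOutcome")
}

#' @export
print.TrioOutcome <- function(x, ...) {
  cat(sprintf("Trio %s/%s: %s\n", x$S, x$T, x$label))
  print(round(x$p, 5))
  invisible(x)
}

#' Aggregate trio outcomes over replicate plates
#'
#' A cause-effect call is emitted only when the same chain pattern holds in
#' at least \code{minSupport} of the replicate dose-zero data sets (default
#' 10 of 27). If both directions independently reach support, no prediction
#' is made and the conflict is recorded.
#'
#' @param outcomes list of \code{TrioOutcome}s (or their labels) for one
#'   trio across replicates.
#' @param minSupport minimum replicate support.
#' @return \code{NULL}, or a list with \code{direction} (\code{"S_to_T"} or
#'   \code{"T_to_S"}), \code{support} and \code{total}; conflicts return
#'   \code{NULL} with attribute \code{conflict = TRUE}.
#' @export
aggregateReplicates <- function(outcomes, minSupport = 10L) {
  if (!length(outcomes)) stop("empty outcome list")
  labels <- vapply(outcomes, function(o)
    if (is.character(o)) o else o$label, character(1))
  nST <- sum(labels == "chain_S_to_T")
  nTS <- sum(labels == "chain_T_to_S")
  if (nST >= minSupport && nTS >= minSupport) {
    message("both directions reach support (", nST, " vs ", nTS,
            "); conflicting trio, no prediction emitted")
    return(NULL)
  }
  if (nST >= minSupport)
    return(list(direction = "S_to_T", support = nST, total = length(labels)))
  if (nTS >= minSupport)
    return(list(direction = "T_to_S", support = nTS, total = length(labels)))
  NULL
}

# all six p-values for every (context, replicate, unordered pair): the raw
# material for run/threshold-sensitivity. Returns a data.frame with one row
# per evaluated trio replicate.
.collectTrioPvalues <- function(bundle, minCells = 20L) {
  tabs <- bundle@tables
  meta <- lapply(tabs, function(tab) tab@meta)
  subpops <- sort(unique(vapply(meta, `[[`, "", "subpopulation")))
  activators <- sort(setdiff(unique(vapply(meta, `[[`, "", "activator")),
                             "reference"))
  inhibitors <- sort(unique(vapply(meta, `[[`, "", "inhibitor")))
  rows <- list()
  for (sp in subpops) {
    for (act in activators) {
      for (inh in inhibitors) {
        ref <- getCondition(bundle, sp, "reference", inh, 0L)
        stim <- getCondition(bundle, sp, act, inh, 0L)
        if (is.null(ref) || is.null(stim)) next
        pooled <- poolActivation(ref, stim, minCells = minCells)
        if (is.null(pooled)) next
        markers <- sort(colnames(pooled@exprs))
        for (i in seq_along(markers)[-length(markers)]) {
          for (j in seq(i + 1, length(markers))) {
            S <- markers[i]
            T <- markers[j]
            p <- .trioPvalues(pooled, S, T)
            rows[[length(rows) + 1L]] <- data.frame(
              subpopulation = sp, activator = act, inhibitor = inh,
              S = S, T = T, t(p), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(subpopulation = character(0), activator = character(0),
                      inhibitor = character(0), S = character(0),
                      T = character(0)))
  do.call(rbind, rows)
}

# turn a raw p-value table into predictions under given thresholds/support
.predictionsFromPvalues <- function(pv, thresholds, minSupport) {
  empty <- data.frame(cause = character(0), effect = character(0),
                      activator = character(0), subpopulation = character(0),
                      support = integer(0), total = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pv)) return(empty)
  pcols <- c("SA", "TA", "ST", "ST.A", "SA.T", "TA.S")
  labels <- vapply(seq_len(nrow(pv)), function(r) {
    p <- unlist(pv[r, pcols])
    names(p) <- pcols
    .trioLabel(p, thresholds)
  }, character(1))
  key <- paste(pv$subpopulation, pv$activator, pv$S, pv$T, sep = "|")
  out <- list()
  for (k in sort(unique(key))) {
    idx <- which(key == k)
    agg <- aggregateReplicates(as.list(labels[idx]), minSupport = minSupport)
    if (is.null(agg)) next
    r <- idx[1]
    cause <- if (agg$direction == "S_to_T") pv$S[r] else pv$T[r]
    effect <- if (agg$direction == "S_to_T") pv$T[r] else pv$S[r]
    out[[length(out) + 1L]] <- data.frame(
      cause = cause, effect = effect, activator = pv$activator[r],
      subpopulation = pv$subpopulation[r], support = agg$support,
      total = length(idx), stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$subpopulation, res$activator, res$cause, res$effect), ,
      drop = FALSE]
}

#' Run conservative local causal discovery on a study
#'
#' For every subpopulation, activator and unordered marker pair, pools the
#' reference and activated dose-zero tables of each inhibitor plate,
#' evaluates the six-test trio pattern on each replicate, and emits a
#' cause-effect prediction when one direction reaches the replicate-support
#' threshold. Undersized conditions (fewer than \code{minCells} cells) are
#' skipped with a message. Output order is deterministic.
#'
#' @param bundle a [StudyBundle-class] with dose-zero reference and
#'   activated tables.
#' @param thresholds a [ciThresholds()] object.
#' @param minSupport minimum number of replicates showing the same chain
#'   pattern (default 10).
#' @param minCells minimum cells per condition table (default 20).
#' @return data.frame with columns \code{cause}, \code{effect},
#'   \code{activator}, \code{subpopulation}, \code{support}, \code{total}.
#' @export
runCLCD <- function(bundle, thresholds = ciThresholds(), minSupport = 10L,
                    minCells = 20L) {
  pv <- .collectTrioPvalues(bundle, minCells = minCells)
  .predictionsFromPvalues(pv, thresholds, minSupport)
}

#' Rank predictions by frequency of appearance
#'
#' Unique cause-effect pairs ranked by the number of contexts (activator,
#' subpopulation, and any other stratum present) in which they appear,
#' descending; ties are broken lexicographically by cause then effect, so
#' the ranking is stable across runs.
#'
#' @param predictions data.frame with columns \code{cause} and
#'   \code{effect} (one row per context appearance).
#' @return data.frame with \code{cause}, \code{effect}, \code{frequency},
#'   sorted by decreasing frequency.
#' @export
rankPredictions <- function(predictions) {
  if (!nrow(predictions))
    return(data.frame(cause = character(0), effect = character(0),
                      frequency = integer(0), stringsAsFactors = FALSE))
  key <- paste(predictions$cause, predictions$effect, sep = "->")
  tab <- table(key)
  parts <- strsplit(names(tab), "->", fixed = TRUE)
  res <- data.frame(cause = vapply(parts, `[`, "", 1),
                    effect = vapply(parts, `[`, "", 2),
                    frequency = as.integer(tab), stringsAsFactors = FALSE)
  res[order(-res$frequency, res$cause, res$effect), , drop = FALSE]
}

#' Sensitivity of the prediction set to the decision thresholds
#'
#' Re-applies the trio decision rule over a grid of (alpha, beta,
#' minSupport) settings using the test p-values computed once, and reports
#' the prediction count and the Jaccard overlap of each setting's
#' predictions with the default-setting predictions.
#'
#' @param bundle a [StudyBundle-class].
#' @param alphaGrid,betaGrid,minSupportGrid parameter grids (full crossing;
#'   every alpha must be below every beta it is paired with).
#' @param default a [ciThresholds()] object defining the reference setting.
#' @param defaultMinSupport reference support threshold.
#' @param minCells minimum cells per condition table.
#' @return data.frame with one row per setting: \code{alpha}, \code{beta},
#'   \code{minSupport}, \code{nPredictions}, \code{jaccard}.
#' @export
thresholdSensitivity <- function(bundle, alphaGrid = c(1e-5, 1e-3, 1e-2),
                                 betaGrid = c(0.15, 0.3, 0.5),
                                 minSupportGrid = 10L,
                                 default = ciThresholds(),
                                 defaultMinSupport = 10L,
                                 minCells = 20L) {
  if (any(vapply(alphaGrid, function(a)
    any(a >= betaGrid), logical(1))))
    stop("invalid grid: every alpha must be smaller than every beta")
  pv <- .collectTrioPvalues(bundle, minCells = minCells)
  predKey <- function(df) paste(df$subpopulation, df$activator, df$cause,
                                df$effect, sep = "|")
  ref <- predKey(.predictionsFromPvalues(pv, default, defaultMinSupport))
  grid <- expand.grid(alpha = alphaGrid, beta = betaGrid,
                      minSupport = minSupportGrid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    th <- ciThresholds(grid$alpha[g], grid$beta[g])
    got <- predKey(.predictionsFromPvalues(pv, th, grid$minSupport[g]))
    un <- length(union(got, ref))
    data.frame(alpha = grid$alpha[g], beta = grid$beta[g],
               minSupport = grid$minSupport[g], nPredictions = length(got),
               jaccard = if (un == 0) 1 else length(intersect(got, ref)) / un)
  })
  do.call(rbind, res)
}
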