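# Ranked-precision evaluation of predictions against a directed ancestry
# ground truth (pathway-database style).

.newAncestryTruth <- function(pairs, provenance = "") {
  pairs <- unique(pairs[pairs$cause != pairs$effect, , drop = FALSE])
  pairs <- pairs[order(pairs$cause, pairs$effect), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 keys = paste(pairs$cause, pairs$effect, sep = "->"),
                 provenance = provenance),
            class = "AncestryTruth")
}

#' @export
print.AncestryTruth <- function(x, ...) {
  cat(sprintf("AncestryTruth: %d directed ancestry pairs over %d proteins (%s)\n",
              nrow(x$pairs),
              length(unique(c(x$pairs$cause, x$pairs$effect))),
              x$provenance))
  invisible(x)
}

# transitive closure of a directed edge list (cycles allowed)
.transitiveClosure <- function(edges) {
  if (!nrow(edges)) return(edges)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  D <- igraph::distances(g, mode = "out")
  idx <- which(is.finite(D) & D > 0, arr.ind = TRUE)
  data.frame(cause = rownames(D)[idx[, 1]], effect = colnames(D)[idx[, 2]],
             stringsAsFactors = FALSE)
}

# minimal KGML reader: entry id -> first token of the name attribute;
# relation entry1 -> entry2 kept for causal subtypes
.readKGML <- function(path, subtypes = c("activation", "inhibition",
                                         "phosphorylation")) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed KGML in '", path, "': ", conditionMessage(e)))
  entries <- xml2::xml_find_all(doc, ".//entry")
  ids <- xml2::xml_attr(entries, "id")
  names <- vapply(entries, function(e) {
    g <- xml2::xml_find_first(e, "./graphics")
    nm <- if (!inherits(g, "xml_missing")) xml2::xml_attr(g, "name") else NA
    if (is.na(nm) || !nzchar(nm)) nm <- xml2::xml_attr(e, "name")
    strsplit(nm, "[, ]+")[[1]][1]
  }, character(1))
  lookup <- stats::setNames(names, ids)
  relations <- xml2::xml_find_all(doc, ".//relation")
  out <- lapply(relations, function(rel) {
    subs <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    if (!any(subs %in% subtypes)) return(NULL)
    data.frame(cause = lookup[[xml2::xml_attr(rel, "entry1")]],
               effect = lookup[[xml2::xml_attr(rel, "entry2")]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(cause = character(0), effect = character(0),
                               stringsAsFactors = FALSE) else out
}

#' Load a directed ancestry ground truth
#'
#' Reads direct causal relations from either a two-column edge list
#' (TSV/CSV: cause, effect; a header line is detected and skipped) or one
#' or more minimal KGML pathway files (directed \code{relation} elements of
#' subtype activation / inhibition / phosphorylation; direction, not sign,
#' is what is evaluated). Protein aliases are mapped through an optional
#' two-column alias table, names are deduplicated, self-pairs dropped, and
#' the relation set is closed transitively (cycles allowed), yielding
#' direct-or-indirect ancestry pairs.
#'
#' @param paths file path(s); \code{.xml}/\code{.kgml} files are parsed as
#'   KGML, anything else as an edge list.
#' @param aliases optional data.frame or two-column file mapping source
#'   names (column 1) to canonical marker names (column 2).
#' @return An \code{"AncestryTruth"} (transitively closed pair set).
#' @export
loadTruth <- function(paths, aliases = NULL) {
  if (inherits(paths, "AncestryTruth")) return(paths)  # idempotent
  edgeList <- lapply(paths, function(path) {
    if (!file.exists(path)) stop("ground-truth file not found: ", path)
    if (grepl("\\.(xml|kgml)$", path, ignore.case = TRUE)) {
      .readKGML(path)
    } else {
      raw <- tryCatch(
        read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE,
                   col.names = c("cause", "effect")),
        error = function(e) data.frame(cause = character(0),
                                       effect = character(0)))
      if (nrow(raw) && identical(tolower(unname(unlist(raw[1, ]))),
                                 c("cause", "effect")))
        raw <- raw[-1, , drop = FALSE]
      raw
    }
  })
  edges <- do.call(rbind, edgeList)
  if (!nrow(edges)) {
    warning("ground truth is empty")
    return(.newAncestryTruth(edges, provenance = paste(paths, collapse = ";")))
  }
  if (!is.null(aliases)) {
    if (is.character(aliases) && length(aliases) == 1)
      aliases <- read.table(aliases, header = FALSE, sep = "",
                            stringsAsFactors = FALSE)
    map <- stats::setNames(as.character(aliases[[2]]),
                           as.character(aliases[[1]]))
    unmapped <- setdiff(unique(c(edges$cause, edges$effect)), names(map))
    if (length(unmapped))
      message("names without alias mapping kept as-is: ",
              paste(unmapped, collapse = ", "))
    remap <- function(x) ifelse(x %in% names(map), map[x], x)
    edges$cause <- remap(edges$cause)
    edges$effect <- remap(edges$effect)
  }
  closed <- .transitiveClosure(edges)
  .newAncestryTruth(closed, provenance = paste(paths, collapse = ";"))
}

#' Build an ancestry truth directly from a causal model
#'
#' The directed ancestry relations of the generating model: marker j is an
#' ancestor of marker i when the (i, j) entry of \eqn{(I-B)^{-1}} is
#' structurally non-zero off the diagonal. Used to evaluate predictions on
#' synthetic studies where the generating model is known.
#'
#' @param model a [CausalModel-class].
#' @return An \code{"AncestryTruth"}.
#' @export
modelAncestryTruth <- function(model) {
  B <- connectivity(model)
  edges <- which(B != 0, arr.ind = TRUE)
  df <- data.frame(cause = model@labels[edges[, 2]],
                   effect = model@labels[edges[, 1]],
                   stringsAsFactors = FALSE)
  .newAncestryTruth(.transitiveClosure(df), provenance = "generating model")
}

#' Precision of a ranked prediction list at every rank
#'
#' Forward precision at rank k is the fraction of the top-k predictions
#' whose (cause, effect) pair is in the ancestry truth; reversed precision
#' uses each prediction's reversed pair. The precision at the full ranking
#' length equals the overall precision regardless of tie-break order.
#'
#' @param ranked data.frame with columns \code{cause}, \code{effect} in
#'   rank order (e.g. from [rankPredictions()]).
#' @param truth an \code{"AncestryTruth"}.
#' @return data.frame with columns \code{k}, \code{precision},
#'   \code{reversedPrecision}.
#' @export
precisionAtRank <- function(ranked, truth) {
  stopifnot(inherits(truth, "AncestryTruth"))
  if (!nrow(ranked)) stop("ranked prediction list is empty")
  fwd <- paste(ranked$cause, ranked$effect, sep = "->") %in% truth$keys
  rev <- paste(ranked$effect, ranked$cause, sep = "->") %in% truth$keys
  k <- seq_len(nrow(ranked))
  data.frame(k = k, precision = cumsum(fwd) / k,
             reversedPrecision = cumsum(rev) / k)
}

#' Precision of predictions versus stratified random baselines
#'
#' Compares the overall precision of a prediction set with \code{nRep}
#' random prediction sets of identical size (and identical per-stratum
#' counts when a stratum column is present), drawn over all ordered marker
#' pairs. Significance is a one-sided z-test:
#' z = (observed - mean random) / sd random.
#'
#' @param predictions data.frame with \code{cause}, \code{effect} and
#'   optionally \code{activator}/\code{subpopulation} strata columns.
#' @param truth an \code{"AncestryTruth"}.
#' @param universe character vector of marker names defining the pair
#'   space.
#' @param nRep number of random sets (>= 2).
#' @param seed integer seed.
#' @return list of class \code{"BaselineTest"}: \code{precision},
#'   \code{randomMean}, \code{randomSD}, \code{z}, \code{p.value},
#'   \code{nRep}.
#' @export
randomBaselineTest <- function(predictions, truth, universe, nRep = 10L,
                               seed = NULL) {
  stopifnot(inherits(truth, "AncestryTruth"))
  if (nRep < 2) stop("nRep must be >= 2")
  if (!nrow(predictions)) stop("empty prediction set")
  prec <- function(df) mean(paste(df$cause, df$effect, sep = "->") %in%
                              truth$keys)
  observed <- prec(predictions)
  strata <- if (all(c("activator", "subpopulation") %in% colnames(predictions)))
    paste(predictions$activator, predictions$subpopulation, sep = "|")
  else rep("all", nrow(predictions))
  counts <- table(strata)
  allPairs <- expand.grid(cause = universe, effect = universe,
                          stringsAsFactors = FALSE)
  allPairs <- allPairs[allPairs$cause != allPairs$effect, , drop = FALSE]
  randomPrec <- .withSeed(seed, vapply(seq_len(nRep), function(r) {
    draws <- lapply(as.integer(counts), function(k)
      allPairs[sample(nrow(allPairs), k), , drop = FALSE])
    prec(do.call(rbind, draws))
  }, numeric(1)))
  mu <- mean(randomPrec)
  s <- sd(randomPrec)
  if (s == 0) {
    warning("zero variance across random baselines; p-value at boundary")
    p <- if (observed > mu) 0 else 1
    z <- if (observed == mu) 0 else sign(observed - mu) * Inf
  } else {
    z <- (observed - mu) / s
    p <- pnorm(z, lower.tail = FALSE)
  }
  structure(list(precision = observed, randomMean = mu, randomSD = s,
                 z = z, p.value = p, nRep = nRep),
            class = "BaselineTest")
}

#' @export
print.BaselineTest <- function(x, ...) {
  cat(sprintf(
    "Precision %.3f vs random %.3f (sd %.3f): z = %.2f, one-sided p = %.3g\n",
    x$precision, x$randomMean, x$randomSD, x$z, x$p.value))
  invisible(x)
}
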