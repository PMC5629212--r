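#' @import methods
#' @importFrom stats rnorm runif var cov sd pt pnorm pchisq qnorm quantile
#'   rbinom t.test complete.cases
#' @importFrom utils read.csv write.csv head
NULL

.offdiag <- function(M) {
  M[row(M) != col(M)]
}

.spectralRadius <- function(B) {
  if (all(B == 0)) return(0)
  max(Mod(eigen(B, only.values = TRUE)$values))
}

.isSymmetricPSD <- function(S, tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = 1e-8)) return(FALSE)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) > -tol * max(abs(ev), 1)
}

#' Linear causal model over a panel of signaling proteins
#'
#' A \code{CausalModel} is the ground truth used by the synthetic-data
#' generator: a linear structural equation model \eqn{x = Bx + aA + \epsilon}
#' over \code{p} continuous markers, with an exogenous binary activation
#' indicator \eqn{A}. \code{B[i, j]} non-zero means marker \code{j} directly
#' causes marker \code{i}; off-diagonal entries of the noise covariance
#' encode latent confounding; non-zero entries of \code{a} are the direct
#' targets of the activator. Cycles are allowed provided the spectral radius
#' of \code{B} is below one, so the equilibrium distribution
#' \eqn{x = (I-B)^{-1}(aA + \epsilon)} exists.
#'
#' @slot B numeric p x p connectivity matrix, zero diagonal.
#' @slot SigmaEps numeric p x p symmetric positive semi-definite noise
#'   covariance.
#' @slot a numeric length-p activator effect vector.
#' @slot labels character length-p marker names.
#'
#' @seealso [makeRandomModel()], [simulateCondition()], [simulateStudy()]
#' @export
setClass("CausalModel",
  representation(
    B = "matrix",
    SigmaEps = "matrix",
    a = "numeric",
    labels = "character"
  )
)

setValidity("CausalModel", function(object) {
  p <- nrow(object@B)
  msg <- character()
  if (ncol(object@B) != p) msg <- c(msg, "B must be square")
  if (p < 1) msg <- c(msg, "B must have at least one variable")
  if (any(diag(object@B) != 0)) msg <- c(msg, "diag(B) must be zero (no self-loops)")
  if (!identical(dim(object@SigmaEps), dim(object@B)))
    msg <- c(msg, "SigmaEps must match dim(B)")
  if (length(object@a) != p) msg <- c(msg, "a must have length p")
  if (length(object@labels) != p) msg <- c(msg, "labels must have length p")
  if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
  if (length(msg)) return(msg)
  if (!.isSymmetricPSD(object@SigmaEps))
    msg <- c(msg, "SigmaEps must be symmetric positive semi-definite")
  if (.spectralRadius(object@B) >= 1)
    msg <- c(msg, "spectral radius of B must be < 1 for a stable equilibrium")
  imb <- diag(p) - object@B
  if (abs(det(imb)) < 1e-12) msg <- c(msg, "(I - B) must be invertible")
  if (length(msg)) msg else TRUE
})

#' Construct a CausalModel
#'
#' @param B p x p connectivity matrix (zero diagonal).
#' @param SigmaEps noise covariance; defaults to the identity.
#' @param a activator effect vector; defaults to all zero.
#' @param labels marker names; defaults to \code{P1..Pp} (or the canonical
#'   14-marker phosphoprotein panel when \code{p == 14}).
#' @return A validated [CausalModel-class] object.
#' @export
causalModel <- function(B, SigmaEps = diag(nrow(B)), a = numeric(nrow(B)),
                        labels = NULL) {
  B <- as.matrix(B)
  p <- nrow(B)
  if (is.null(labels)) labels <- defaultMarkers(p)
  SigmaEps <- as.matrix(SigmaEps)
  dimnames(B) <- list(labels, labels)
  dimnames(SigmaEps) <- list(labels, labels)
  names(a) <- labels
  new("CausalModel", B = B, SigmaEps = SigmaEps, a = as.numeric(a),
      labels = labels)
}

#' Marker labels for a model size
#'
#' For fourteen markers, the canonical functional phosphoprotein panel of
#' PBMC signaling studies is used; otherwise generic \code{P1..Pp} names.
#'
#' @param p number of markers.
#' @return Character vector of length \code{p}.
#' @export
defaultMarkers <- function(p) {
  panel14 <- c("pNFkB", "pp38", "pStat5", "pAkt", "pStat1", "pSHP2",
               "pZap70", "pStat3", "pSlp76", "pBtk", "pPlcg2", "pErk",
               "pLat", "pS6")
  if (p == 14L) panel14 else paste0("P", seq_len(p))
}

#' @describeIn CausalModel-class number of markers.
#' @param object,x a \code{CausalModel}.
#' @export
setMethod("length", "CausalModel", function(x) nrow(x@B))

#' Accessors for CausalModel
#'
#' \code{connectivity} returns the direct-effect matrix B,
#' \code{noiseCovariance} the noise covariance, \code{activatorEffects} the
#' activator target vector, and \code{markerNames} the marker labels.
#'
#' @param model a [CausalModel-class].
#' @return The corresponding slot.
#' @export
connectivity <- function(model) model@B

#' @rdname connectivity
#' @export
noiseCovariance <- function(model) model@SigmaEps

#' @rdname connectivity
#' @export
activatorEffects <- function(model) model@a

#' @rdname connectivity
#' @export
markerNames <- function(model) model@labels

setMethod("show", "CausalModel", function(object) {
  p <- nrow(object@B)
  cat("CausalModel with", p, "markers\n")
  cat("  edges:", sum(object@B != 0), "directed;",
      sum(.offdiag(object@SigmaEps) != 0) / 2, "confounded pairs\n")
  cat("  activator targets:", paste(object@labels[object@a != 0],
                                    collapse = ", "), "\n")
  acyclic <- tryCatch(!is.null(.topologicalOrder(object@B)),
                      error = function(e) FALSE)
  cat("  structure:", if (acyclic) "acyclic" else "cyclic",
      sprintf("(spectral radius %.3f)\n", .spectralRadius(object@B)))
})

# topological order of variables given B (B[i,j] != 0 <=> j -> i);
# NULL when cyclic
.topologicalOrder <- function(B) {
  adj <- B != 0
  order <- integer(0)
  remaining <- seq_len(nrow(B))
  while (length(remaining)) {
    # a source: no remaining parent, i.e. row j all-FALSE among remaining
    noParent <- vapply(remaining, function(j) !any(adj[j, remaining]),
                       logical(1))
    if (!any(noParent)) return(NULL)
    order <- c(order, remaining[noParent])
    remaining <- remaining[!noParent]
  }
  order
}

#' Single-cell table for one experimental condition
#'
#' One gated condition of a perturbation study: an \code{n x p} matrix of
#' cells by markers, the condition metadata (subpopulation, activator,
#' inhibitor, dosage index, replicate/plate), and an optional per-cell
#' binary activation column (present in pooled reference+activated tables).
#'
#' @slot exprs numeric cells x markers matrix with marker column names.
#' @slot activation integer per-cell activation indicator (0/1), or
#'   length-zero when the condition is homogeneous.
#' @slot meta list with entries \code{subpopulation}, \code{activator},
#'   \code{inhibitor}, \code{dosage}, \code{replicate}.
#' @export
setClass("CellTable",
  representation(
    exprs = "matrix",
    activation = "integer",
    meta = "list"
  )
)

setValidity("CellTable", function(object) {
  msg <- character()
  if (nrow(object@exprs) < 1) msg <- c(msg, "at least one cell required")
  if (is.null(colnames(object@exprs))) msg <- c(msg, "marker names required")
  if (length(object@activation) &&
      length(object@activation) != nrow(object@exprs))
    msg <- c(msg, "activation must have one entry per cell")
  if (length(object@activation) && !all(object@activation %in% c(0L, 1L)))
    msg <- c(msg, "activation must be binary 0/1")
  need <- c("subpopulation", "activator", "inhibitor", "dosage", "replicate")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta must contain:", paste(need, collapse = ", ")))
  dosage <- object@meta$dosage
  if (!is.null(dosage) && (dosage < 0))
    msg <- c(msg, "dosage index must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CellTable
#'
#' @param exprs cells x markers numeric matrix (marker column names required).
#' @param subpopulation,activator,inhibitor,dosage,replicate condition
#'   metadata. \code{activator = "reference"} denotes the unstimulated
#'   condition.
#' @param activation optional per-cell 0/1 vector for pooled tables.
#' @return A validated [CellTable-class].
#' @export
cellTable <- function(exprs, subpopulation = "pop1", activator = "reference",
                      inhibitor = "inh1", dosage = 0L, replicate = inhibitor,
                      activation = integer(0)) {
  new("CellTable", exprs = as.matrix(exprs),
      activation = as.integer(activation),
      meta = list(subpopulation = subpopulation, activator = activator,
                  inhibitor = inhibitor, dosage = as.integer(dosage),
                  replicate = replicate))
}

#' @describeIn CellTable-class number of cells.
#' @param x,object a \code{CellTable}.
#' @export
setMethod("nrow", "CellTable", function(x) nrow(x@exprs))

#' Accessors for CellTable
#'
#' @param table a [CellTable-class].
#' @return \code{cellValues}: the cells x markers matrix; \code{cellMeta}:
#'   the metadata list; \code{activationStatus}: the per-cell 0/1 vector
#'   (length zero if absent).
#' @export
cellValues <- function(table) table@exprs

#' @rdname cellValues
#' @export
cellMeta <- function(table) table@meta

#' @rdname cellValues
#' @export
activationStatus <- function(table) table@activation

setMethod("show", "CellTable", function(object) {
  m <- object@meta
  cat(sprintf("CellTable: %d cells x %d markers [%s | %s | %s | D%d]\n",
              nrow(object@exprs), ncol(object@exprs), m$subpopulation,
              m$activator, m$inhibitor, m$dosage))
  if (length(object@activation))
    cat(sprintf("  pooled, %.0f%% activated\n", 100 * mean(object@activation)))
})

#' A full perturbation study
#'
#' A keyed collection of [CellTable-class] objects covering the
#' activator x inhibitor x dosage x replicate design, mirroring the layout
#' of multiplexed inhibitor-titration mass-cytometry studies: for every
#' subpopulation, an unstimulated reference and activated conditions across
#' inhibitor plates and dosage indices, where the dose-zero plates form
#' replicates of the same distribution.
#'
#' Keys are \code{subpopulation|activator|inhibitor|dosage}.
#'
#' @slot tables named list of \code{CellTable}.
#' @slot design list describing the study design (subpopulations, activators,
#'   inhibitors with dosage schedules, dosage count, sample-size rule).
#' @slot modelHash character fingerprint of the generating model (empty for
#'   imported studies).
#' @export
setClass("StudyBundle",
  representation(
    tables = "list",
    design = "list",
    modelHash = "character"
  )
)

.conditionKey <- function(subpopulation, activator, inhibitor, dosage) {
  paste(subpopulation, activator, inhibitor, sprintf("D%d", as.integer(dosage)),
        sep = "|")
}

setValidity("StudyBundle", function(object) {
  msg <- character()
  if (length(object@tables)) {
    if (is.null(names(object@tables)) || anyDuplicated(names(object@tables)))
      msg <- c(msg, "tables must be uniquely named by condition key")
    ok <- vapply(seq_along(object@tables), function(i) {
      tab <- object@tables[[i]]
      m <- tab@meta
      identical(names(object@tables)[i],
                .conditionKey(m$subpopulation, m$activator, m$inhibitor,
                              m$dosage))
    }, logical(1))
    if (!all(ok)) msg <- c(msg, "every table's meta must match its key")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StudyBundle from a list of CellTables
#'
#' @param tables list of [CellTable-class]; names are derived from each
#'   table's metadata.
#' @param design design metadata list.
#' @param modelHash fingerprint of the generating model.
#' @return A [StudyBundle-class].
#' @export
studyBundle <- function(tables, design = list(), modelHash = "") {
  keys <- vapply(tables, function(tab) {
    m <- tab@meta
    .conditionKey(m$subpopulation, m$activator, m$inhibitor, m$dosage)
  }, character(1))
  names(tables) <- keys
  new("StudyBundle", tables = tables[order(keys)], design = design,
      modelHash = modelHash)
}

#' @describeIn StudyBundle-class number of condition tables.
#' @param x,object a \code{StudyBundle}.
#' @export
setMethod("length", "StudyBundle", function(x) length(x@tables))

#' Accessors for StudyBundle
#'
#' @param bundle a [StudyBundle-class].
#' @param subpopulation,activator,inhibitor,dosage condition coordinates.
#' @return \code{conditionKeys}: all keys; \code{getCondition}: one
#'   \code{CellTable} or \code{NULL}; \code{studyDesign}: the design list;
#'   \code{studyTables}: the named list of tables.
#' @export
conditionKeys <- function(bundle) names(bundle@tables)

#' @rdname conditionKeys
#' @export
getCondition <- function(bundle, subpopulation, activator, inhibitor, dosage) {
  key <- .conditionKey(subpopulation, activator, inhibitor, dosage)
  if (key %in% names(bundle@tables)) bundle@tables[[key]] else NULL
}

#' @rdname conditionKeys
#' @export
studyDesign <- function(bundle) bundle@design

#' @rdname conditionKeys
#' @export
studyTables <- function(bundle) bundle@tables

setMethod("show", "StudyBundle", function(object) {
  cat("StudyBundle with", length(object@tables), "condition tables\n")
  if (length(object@tables)) {
    meta <- lapply(object@tables, function(tab) tab@meta)
    cat("  subpopulations:",
        paste(unique(vapply(meta, `[[`, "", "subpopulation")), collapse = ", "),
        "\n")
    cat("  activators:",
        paste(unique(vapply(meta, `[[`, "", "activator")), collapse = ", "),
        "\n")
    cat("  inhibitors:",
        length(unique(vapply(meta, `[[`, "", "inhibitor"))),
        " dosages:", length(unique(vapply(meta, function(m) m$dosage, 0L))),
        "\n")
    n <- vapply(object@tables, function(tab) nrow(tab@exprs), 0L)
    cat(sprintf("  cells per condition: %d-%d (total %d)\n",
                min(n), max(n), sum(n)))
  }
})

#' Coerce a study to a SummarizedExperiment
#'
#' Assembles all condition tables into one markers x cells
#' \linkS4class{SummarizedExperiment} with assay \code{"exprs"} and the
#' condition metadata (plus any per-cell activation status) in
#' \code{colData}, for interoperability with single-cell tooling.
#'
#' @param bundle a [StudyBundle-class].
#' @return A \code{SummarizedExperiment}.
#' @export
asSummarizedExperiment <- function(bundle) {
  tabs <- bundle@tables
  stopifnot(length(tabs) > 0)
  mats <- lapply(tabs, function(tab) t(tab@exprs))
  cd <- do.call(rbind, lapply(names(tabs), function(key) {
    tab <- tabs[[key]]
    n <- nrow(tab@exprs)
    act <- if (length(tab@activation)) tab@activation else rep(NA_integer_, n)
    data.frame(
      subpopulation = rep(tab@meta$subpopulation, n),
      activator = rep(tab@meta$activator, n),
      inhibitor = rep(tab@meta$inhibitor, n),
      dosage = rep(tab@meta$dosage, n),
      replicate = rep(tab@meta$replicate, n),
      activation = act,
      stringsAsFactors = FALSE
    )
  }))
  mat <- do.call(cbind, mats)
  colnames(mat) <- sprintf("cell%06d", seq_len(ncol(mat)))
  rownames(cd) <- colnames(mat)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(design = bundle@design, modelHash = bundle@modelHash)
  )
}

#' Estimated connectivity from shift-intervention environments
#'
#' Result of joint-diagonalization estimation: the estimated direct-effect
#' matrix, per-environment intervention-variance estimates, and the attained
#' off-diagonal residual of the joint diagonalization (a model-fit
#' diagnostic; large residuals indicate violated assumptions).
#'
#' @slot Bhat numeric p x p estimate with zero diagonal.
#' @slot interventionVariances numeric environments x p matrix of estimated
#'   shift-intervention variances (non-negative).
#' @slot residual numeric scale-normalized off-diagonal residual.
#' @slot labels character marker names.
#' @export
setClass("ConnectivityEstimate",
  representation(
    Bhat = "matrix",
    interventionVariances = "matrix",
    residual = "numeric",
    labels = "character"
  )
)

setValidity("ConnectivityEstimate", function(object) {
  msg <- character()
  if (any(diag(object@Bhat) != 0)) msg <- c(msg, "diag(Bhat) must be zero")
  if (ncol(object@interventionVariances) != nrow(object@Bhat))
    msg <- c(msg, "interventionVariances must have p columns")
  if (any(object@interventionVariances < 0))
    msg <- c(msg, "intervention variances must be non-negative")
  if (object@residual < 0) msg <- c(msg, "residual must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Accessors for ConnectivityEstimate
#'
#' @param estimate a [ConnectivityEstimate-class].
#' @return \code{estimatedConnectivity}: the p x p coefficient matrix;
#'   \code{interventionVariances}: environments x p variance estimates;
#'   \code{diagonalizationResidual}: the normalized residual.
#' @export
estimatedConnectivity <- function(estimate) estimate@Bhat

#' @rdname estimatedConnectivity
#' @export
interventionVariances <- function(estimate) estimate@interventionVariances

#' @rdname estimatedConnectivity
#' @export
diagonalizationResidual <- function(estimate) estimate@residual

setMethod("show", "ConnectivityEstimate", function(object) {
  cat(sprintf("ConnectivityEstimate: %d markers, %d environments\n",
              nrow(object@Bhat), nrow(object@interventionVariances)))
  cat(sprintf("  diagonalization residual: %.3g\n", object@residual))
  nz <- sum(abs(object@Bhat) > 0.05)
  cat(sprintf("  |coefficient| > 0.05: %d entries\n", nz))
})
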