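# Synthetic single-cell perturbation studies from known linear causal models.

# evaluate expr under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic 31-polynomial string hash, kept below 2^31 - 1
.stringHash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# seed for one condition, derived from the master seed and the condition key
.conditionSeed <- function(masterSeed, key) {
  as.integer((as.numeric(masterSeed) * 7919 + .stringHash(key)) %% 2147483647)
}

#' Draw a random linear causal model
#'
#' Samples a [CausalModel-class] with the given edge density, optional latent
#' confounding (rank-one additions to the noise covariance), optional cycles,
#' and a random set of activator targets. Coefficient magnitudes are drawn
#' uniformly from \code{coefRange} with random sign; the default floor of 0.3
#' keeps near-faithfulness violations improbable.
#'
#' @param p number of markers (>= 2).
#' @param edgeDensity probability of each feasible directed edge, in [0, 1].
#' @param confounderDensity probability that an unordered marker pair shares
#'   a latent confounder, in [0, 1].
#' @param cyclic if \code{TRUE}, edges are sampled over all ordered pairs and
#'   the model is accepted only when the spectral radius of B is below one
#'   (bounded retries); if \code{FALSE}, B is strictly triangular under a
#'   random variable order.
#' @param activatorOutDegree number of markers directly shifted by the
#'   activator.
#' @param coefRange magnitude range of causal coefficients.
#' @param activatorRange magnitude range of activator effects (positive:
#'   activation increases phosphorylation).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param maxTries retries for cyclic models before failing.
#' @return A [CausalModel-class].
#' @export
makeRandomModel <- function(p, edgeDensity = 0.2, confounderDensity = 0,
                            cyclic = FALSE, activatorOutDegree = 1,
                            coefRange = c(0.3, 0.9),
                            activatorRange = c(0.8, 1.5),
                            seed = NULL, maxTries = 50L) {
  if (p < 2) stop("a causal model needs at least p = 2 variables")
  stopifnot(edgeDensity >= 0, edgeDensity <= 1,
            confounderDensity >= 0, confounderDensity <= 1,
            activatorOutDegree >= 0, activatorOutDegree <= p)
  .withSeed(seed, {
    labels <- defaultMarkers(p)
    drawCoef <- function(k) {
      sample(c(-1, 1), k, replace = TRUE) * runif(k, coefRange[1], coefRange[2])
    }
    B <- NULL
    if (!cyclic) {
      ord <- sample(p)  # ord[k] = variable at causal position k
      B <- matrix(0, p, p)
      for (i in seq_len(p - 1)) {
        for (j in seq(i + 1, p)) {
          if (runif(1) < edgeDensity) {
            # earlier position i causes later position j
            B[ord[j], ord[i]] <- drawCoef(1)
          }
        }
      }
    } else {
      for (try in seq_len(maxTries)) {
        cand <- matrix(0, p, p)
        off <- which(row(cand) != col(cand))
        sel <- off[runif(length(off)) < edgeDensity]
        cand[sel] <- drawCoef(length(sel))
        if (.spectralRadius(cand) < 1) {
          B <- cand
          break
        }
      }
      if (is.null(B))
        stop("could not draw a stable cyclic B (spectral radius >= 1) in ",
             maxTries, " tries; lower edgeDensity or coefRange")
    }
    SigmaEps <- diag(p)
    pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    for (r in seq_len(nrow(pairs))) {
      if (runif(1) < confounderDensity) {
        lam <- numeric(p)
        lam[pairs[r, ]] <- runif(2, 0.5, 1)
        SigmaEps <- SigmaEps + lam %o% lam  # rank-one latent source: PSD
      }
    }
    a <- numeric(p)
    if (activatorOutDegree > 0) {
      targets <- sample(p, activatorOutDegree)
      a[targets] <- runif(activatorOutDegree, activatorRange[1],
                          activatorRange[2])
    }
    causalModel(B, SigmaEps, a, labels)
  })
}

#' Population covariance of the equilibrium distribution
#'
#' Closed-form covariance of \eqn{x = (I-B)^{-1}(aA + c + \epsilon)}:
#' \eqn{(I-B)^{-1}(\Sigma_\epsilon + \Sigma_c + var(A)\,a a^T)(I-B)^{-T}}.
#' Used as the oracle for the generator and for population-level
#' joint-diagonalization checks.
#'
#' @param model a [CausalModel-class].
#' @param interventionVariances length-p vector, the diagonal of the
#'   shift-intervention covariance (default zero).
#' @param activationVar variance of the binary activation indicator
#'   (\code{0} when the condition is homogeneous; \code{q(1-q)} for a pooled
#'   table with activation probability \code{q}).
#' @return p x p covariance matrix.
#' @export
populationCovariance <- function(model, interventionVariances = NULL,
                                 activationVar = 0) {
  p <- length(model@a)
  if (is.null(interventionVariances)) interventionVariances <- numeric(p)
  stopifnot(length(interventionVariances) == p,
            all(interventionVariances >= 0))
  M <- solve(diag(p) - model@B)
  inner <- model@SigmaEps + diag(interventionVariances, p) +
    activationVar * (model@a %o% model@a)
  S <- M %*% inner %*% t(M)
  dimnames(S) <- list(model@labels, model@labels)
  S
}

# n draws from MVN(0, Sigma) via the (pivoted-safe) Cholesky factor
.rmvnorm <- function(n, Sigma) {
  p <- ncol(Sigma)
  ch <- tryCatch(chol(Sigma), error = function(e) {
    ee <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
    vals <- pmax(ee$values, 0)
    t(ee$vectors %*% (sqrt(vals) * t(ee$vectors)))
  })
  matrix(rnorm(n * p), n, p) %*% ch
}

#' Simulate one experimental condition
#'
#' Draws \code{n} i.i.d. cells from the equilibrium of the linear model
#' under a shift intervention with the given per-marker variances, with or
#' without the activator. The population covariance is the closed form
#' returned by [populationCovariance()].
#'
#' @param model a [CausalModel-class].
#' @param interventionVariances length-p non-negative vector (default zero:
#'   purely observational).
#' @param activated logical: apply the activator mean shift \code{a}?
#' @param n number of cells (>= 1).
#' @param seed optional integer seed.
#' @param subpopulation,activator,inhibitor,dosage,replicate condition
#'   metadata recorded on the table (\code{activator} defaults to
#'   \code{"reference"} when not activated).
#' @return A [CellTable-class].
#' @export
simulateCondition <- function(model, interventionVariances = NULL,
                              activated = FALSE, n, seed = NULL,
                              subpopulation = "pop1",
                              activator = if (activated) "act1" else "reference",
                              inhibitor = "inh1", dosage = 0L,
                              replicate = inhibitor) {
  p <- length(model@a)
  if (n < 1) stop("n must be >= 1")
  if (is.null(interventionVariances)) interventionVariances <- numeric(p)
  stopifnot(length(interventionVariances) == p)
  if (any(interventionVariances < 0))
    stop("intervention variances must be >= 0")
  .withSeed(seed, {
    M <- solve(diag(p) - model@B)
    E <- .rmvnorm(n, model@SigmaEps)
    act <- if (activated) 1L else 0L
    shift <- E
    pos <- which(interventionVariances > 0)
    if (length(pos)) {
      C <- matrix(0, n, p)
      C[, pos] <- matrix(rnorm(n * length(pos)), n) *
        rep(sqrt(interventionVariances[pos]), each = n)
      shift <- shift + C
    }
    if (activated) shift <- shift + matrix(model@a, n, p, byrow = TRUE)
    X <- shift %*% t(M)
    colnames(X) <- model@labels
    cellTable(X, subpopulation = subpopulation, activator = activator,
              inhibitor = inhibitor, dosage = dosage, replicate = replicate)
  })
}

#' Build a study design
#'
#' Describes the perturbation layout the generator reproduces: for each
#' subpopulation and inhibitor plate, an unstimulated reference plus
#' activated conditions across a ladder of inhibitor dosages. Dosage zero
#' carries no intervention on any plate, so the dose-zero tables across
#' inhibitors are i.i.d. replicates of the same distribution. Inhibitor
#' dosage schedules model shift interventions with unknown targets whose
#' variance grows linearly with the dosage index.
#'
#' The defaults mirror a multiplexed inhibitor-titration study of PBMC
#' signaling: 11 activators, 27 inhibitor plates, 8 dosage indices
#' (D0..D7), and per-condition cell counts drawn log-uniformly between 8
#' and 300 cells.
#'
#' @param model a [CausalModel-class]; activator effect vectors are drawn
#'   per activator with the model's own \code{a} used for the first.
#' @param nActivators,nInhibitors,nDosages design dimensions.
#' @param subpopulations character vector of subpopulation labels.
#' @param nPerCondition either a single count, a length-2 range for
#'   log-uniform draws, or a function(key) returning a count (0 drops the
#'   condition).
#' @param inhibitorTargets number of markers targeted by each inhibitor.
#' @param doseStrength intervention variance added per dosage step on each
#'   targeted marker.
#' @param seed integer seed for the design randomness (activator vectors,
#'   inhibitor targets).
#' @return A design list consumed by [simulateStudy()].
#' @export
makeStudyDesign <- function(model, nActivators = 11, nInhibitors = 27,
                            nDosages = 8, subpopulations = "pop1",
                            nPerCondition = c(8, 300),
                            inhibitorTargets = 2, doseStrength = 0.5,
                            seed = NULL) {
  stopifnot(nActivators >= 1, nInhibitors >= 1, nDosages >= 1)
  p <- length(model@a)
  .withSeed(seed, {
    activators <- vector("list", nActivators)
    names(activators) <- paste0("act", seq_len(nActivators))
    activators[[1]] <- model@a
    if (nActivators > 1) {
      for (k in seq(2, nActivators)) {
        a <- numeric(p)
        deg <- max(1L, sum(model@a != 0))
        a[sample(p, deg)] <- runif(deg, 0.8, 1.5)
        activators[[k]] <- a
      }
    }
    inhibitors <- vector("list", nInhibitors)
    names(inhibitors) <- paste0("inh", seq_len(nInhibitors))
    for (k in seq_len(nInhibitors)) {
      targets <- sample(p, min(inhibitorTargets, p))
      sched <- matrix(0, nDosages, p, dimnames = list(
        sprintf("D%d", seq_len(nDosages) - 1L), model@labels))
      for (d in seq_len(nDosages)[-1]) {
        sched[d, targets] <- doseStrength * (d - 1L)
      }
      inhibitors[[k]] <- sched
    }
    list(subpopulations = subpopulations, activators = activators,
         inhibitors = inhibitors, nDosages = nDosages,
         nPerCondition = nPerCondition, referenceLabel = "reference")
  })
}

# number of cells for one condition under the design's sampling rule
.conditionN <- function(nPerCondition, key, seed) {
  if (is.function(nPerCondition)) return(as.integer(nPerCondition(key)))
  if (length(nPerCondition) == 1) return(as.integer(nPerCondition))
  lo <- log(nPerCondition[1])
  hi <- log(nPerCondition[2])
  .withSeed(seed, as.integer(round(exp(runif(1, lo, hi)))))
}

#' Simulate a full perturbation study
#'
#' Generates one [CellTable-class] per (subpopulation, activator-or-
#' reference, inhibitor, dosage) cell of the design. Per-condition seeds are
#' derived deterministically from the master seed and the condition key, so
#' a fixed seed reproduces the study byte-identically. Conditions whose
#' sample-size rule returns zero are dropped with a message.
#'
#' @param model a [CausalModel-class].
#' @param design a design list from [makeStudyDesign()].
#' @param seed master integer seed.
#' @return A [StudyBundle-class].
#' @export
simulateStudy <- function(model, design, seed = 1L) {
  if (is.null(design$activators) || !length(design$activators) ||
      is.null(design$inhibitors) || !length(design$inhibitors))
    stop("empty design: activators and inhibitors are required")
  p <- length(model@a)
  tables <- list()
  skipped <- character(0)
  for (sp in design$subpopulations) {
    for (inh in names(design$inhibitors)) {
      sched <- design$inhibitors[[inh]]
      stopifnot(ncol(sched) == p)
      for (d in seq_len(nrow(sched)) - 1L) {
        iv <- sched[d + 1L, ]
        conds <- c(list(reference = NULL), design$activators)
        names(conds)[1] <- design$referenceLabel %||% "reference"
        for (actName in names(conds)) {
          key <- .conditionKey(sp, actName, inh, d)
          cseed <- .conditionSeed(seed, key)
          # a distinct derived seed for the sample-size draw keeps the cell
          # values independent of the n draw
          n <- .conditionN(design$nPerCondition, key, cseed + 1L)
          if (n < 1) {
            skipped <- c(skipped, key)
            next
          }
          activated <- !is.null(conds[[actName]])
          m <- model
          if (activated) m@a <- as.numeric(conds[[actName]])
          tables[[key]] <- simulateCondition(
            m, interventionVariances = iv, activated = activated, n = n,
            seed = cseed, subpopulation = sp, activator = actName,
            inhibitor = inh, dosage = d, replicate = inh)
        }
      }
    }
  }
  if (length(skipped))
    message("dropped ", length(skipped), " empty condition(s): ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  if (!length(tables)) stop("design produced no conditions")
  studyBundle(tables, design = design, modelHash = .modelHash(model))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cheap deterministic fingerprint of a model
.modelHash <- function(model) {
  s <- paste(c(sprintf("%.10g", c(model@B, model@SigmaEps, model@a)),
               model@labels), collapse = ",")
  sprintf("%08x", .stringHash(s))
}

.sanitizeKey <- function(key) gsub("[^A-Za-z0-9_.-]", "_", key)

#' Write / read a study as CSV + manifest
#'
#' \code{writeStudy} writes one CSV per condition (header: marker labels,
#' plus an \code{activation} column when present; values with 9 significant
#' digits) and a \code{manifest.json} listing every condition's key,
#' metadata, file, cell count and the marker panel. \code{readStudy} reads
#' the manifest back, validates each file against it, and reconstructs the
#' bundle.
#'
#' @param bundle a [StudyBundle-class].
#' @param dir directory to write to / read from.
#' @return \code{writeStudy}: the directory, invisibly. \code{readStudy}:
#'   a [StudyBundle-class].
#' @export
writeStudy <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- bundle@tables
  markers <- colnames(tabs[[1]]@exprs)
  entries <- lapply(names(tabs), function(key) {
    tab <- tabs[[key]]
    file <- paste0(.sanitizeKey(key), ".csv")
    df <- as.data.frame(apply(tab@exprs, 2, function(x)
      sprintf("%.9g", x)), stringsAsFactors = FALSE)
    if (nrow(tab@exprs) == 1)  # apply() drops to vector for one row
      df <- as.data.frame(as.list(sprintf("%.9g", tab@exprs[1, ])),
                          col.names = markers)
    colnames(df) <- markers
    if (length(tab@activation)) df$activation <- tab@activation
    write.csv(df, file.path(dir, file), row.names = FALSE, quote = FALSE)
    c(tab@meta[c("subpopulation", "activator", "inhibitor", "dosage",
                 "replicate")],
      list(key = key, file = file, n = nrow(tab@exprs),
           pooled = length(tab@activation) > 0))
  })
  manifest <- list(markers = markers, modelHash = bundle@modelHash,
                   design = .designSummary(bundle@design),
                   conditions = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

.designSummary <- function(design) {
  if (!length(design)) return(list())
  list(subpopulations = design$subpopulations,
       activators = names(design$activators),
       inhibitors = names(design$inhibitors),
       nDosages = design$nDosages)
}

#' @rdname writeStudy
#' @export
readStudy <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("no manifest.json in '", dir, "': not a study directory")
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  markers <- unlist(manifest$markers)
  if (!length(manifest$conditions)) stop("manifest lists no conditions")
  tables <- lapply(manifest$conditions, function(entry) {
    path <- file.path(dir, entry$file)
    if (!file.exists(path)) stop("missing condition file: ", entry$file)
    df <- read.csv(path, check.names = FALSE)
    hasAct <- "activation" %in% colnames(df)
    got <- setdiff(colnames(df), "activation")
    if (!identical(got, markers))
      stop("marker columns in '", entry$file,
           "' do not match the manifest panel")
    if (nrow(df) != entry$n)
      stop("cell count in '", entry$file, "' does not match the manifest")
    cellTable(as.matrix(df[, markers, drop = FALSE]),
              subpopulation = entry$subpopulation,
              activator = entry$activator, inhibitor = entry$inhibitor,
              dosage = entry$dosage, replicate = entry$replicate,
              activation = if (hasAct) as.integer(df$activation)
                           else integer(0))
  })
  studyBundle(tables, design = list(), modelHash = manifest$modelHash %||% "")
}
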