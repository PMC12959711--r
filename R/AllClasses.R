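#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom stats cor var sd rnorm runif rbinom quantile predict p.adjust
#'   wilcox.test pt prcomp aggregate setNames dist
#' @importFrom utils head
NULL

#' ConnectomeSet: multisite functional-connectivity data container
#'
#' An S4 container for a cohort of subject-level functional-connectivity
#' matrices together with their phenotype table. It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single assay `"fcz"`
#' holding the Fisher-z edge values (rows = undirected ROI pairs in the
#' canonical order of [utPairs()], columns = subjects). `rowData()` records
#' the ROI index pair of every edge; `colData()` holds the phenotype
#' (required columns `subject_id`, `site`, `diagnosis`; optional covariates
#' such as `age`, `sex`, `education`, `motion`, and symptom item scores).
#'
#' Storing only the upper triangle guarantees the symmetry and zero-diagonal
#' invariants of every connectivity matrix by construction; use
#' [fcMatrix()] to materialize a subject's full n x n matrix.
#'
#' @slot nRois integer, number of ROIs.
#' @slot roiLabels character, one label per ROI.
#' @export
setClass("ConnectomeSet",
  contains = "SummarizedExperiment",
  representation(nRois = "integer", roiLabels = "character")
)

setValidity("ConnectomeSet", function(object) {
  msg <- NULL
  n <- object@nRois
  if (length(n) != 1L || n < 2L) msg <- c(msg, "nRois must be a single integer >= 2")
  if (!"fcz" %in% SummarizedExperiment::assayNames(object)) {
    msg <- c(msg, "assay 'fcz' is required")
  } else {
    a <- SummarizedExperiment::assay(object, "fcz")
    if (nrow(a) != n * (n - 1) / 2) {
      msg <- c(msg, "assay row count must equal n*(n-1)/2")
    }
    if (!all(is.finite(a))) msg <- c(msg, "edge values must be finite")
  }
  if (length(object@roiLabels) != n) msg <- c(msg, "roiLabels length must equal nRois")
  cd <- SummarizedExperiment::colData(object)
  req <- c("subject_id", "site", "diagnosis")
  miss <- setdiff(req, colnames(cd))
  if (length(miss)) msg <- c(msg, paste("missing phenotype columns:", paste(miss, collapse = ", ")))
  if ("subject_id" %in% colnames(cd) && anyDuplicated(cd$subject_id)) {
    msg <- c(msg, "subject_id must be unique")
  }
  if ("diagnosis" %in% colnames(cd) && !all(cd$diagnosis %in% c(0, 1))) {
    msg <- c(msg, "diagnosis must be coded 0 (control) / 1 (case)")
  }
  if (is.null(msg)) TRUE else msg
})

#' BrainGraph: binarized connectivity graph for one subject
#'
#' The model input: a binary adjacency matrix (top-percentile absolute
#' connectivity), the node-feature matrix whose row k is the subject's
#' connectivity profile of ROI k, and the diagnostic label.
#'
#' @slot adjacency n x n binary symmetric matrix, zero diagonal.
#' @slot features n x n numeric node-feature matrix (row per node).
#' @slot label numeric, 0 = control, 1 = case (NA allowed for unlabeled).
#' @export
setClass("BrainGraph",
  representation(adjacency = "matrix", features = "matrix", label = "numeric")
)

setValidity("BrainGraph", function(object) {
  A <- object@adjacency
  X <- object@features
  msg <- NULL
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0/1")
  if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
  if (!isTRUE(all.equal(A, t(A), tolerance = 0))) msg <- c(msg, "adjacency must be symmetric")
  if (!identical(dim(A), dim(X))) msg <- c(msg, "features must match adjacency dimensions")
  if (!all(is.finite(X))) msg <- c(msg, "features must be finite")
  if (length(object@label) != 1L) msg <- c(msg, "label must be length 1")
  if (is.null(msg)) TRUE else msg
})

#' CombatModel: fitted empirical-Bayes harmonization model
#'
#' Stores everything needed to apply location/scale site harmonization to new
#' subjects without refitting: the grand mean and covariate coefficients of
#' the edge-wise linear model, the pooled residual variance used for
#' standardization, and the empirical-Bayes shrunken additive (`gammaStar`)
#' and multiplicative (`deltaStar`) site effects for every training site.
#'
#' @slot grandMean numeric, per-edge grand mean (weighted over sites).
#' @slot beta numeric matrix, covariates x edges coefficients.
#' @slot pooledVar numeric, per-edge pooled residual variance.
#' @slot gammaStar numeric matrix, sites x edges additive site effects.
#' @slot deltaStar numeric matrix, sites x edges multiplicative site effects.
#' @slot siteLevels character, training site labels (rows of gamma/delta).
#' @slot covariateNames character, covariate column names (rows of beta).
#' @slot nPerSite integer, training subjects per site.
#' @export
setClass("CombatModel",
  representation(
    grandMean = "numeric", beta = "matrix", pooledVar = "numeric",
    gammaStar = "matrix", deltaStar = "matrix",
    siteLevels = "character", covariateNames = "character",
    nPerSite = "integer"
  )
)

setValidity("CombatModel", function(object) {
  msg <- NULL
  if (any(object@deltaStar <= 0)) msg <- c(msg, "deltaStar must be strictly positive")
  if (nrow(object@gammaStar) != length(object@siteLevels)) {
    msg <- c(msg, "one gammaStar row per training site required")
  }
  if (!identical(dim(object@gammaStar), dim(object@deltaStar))) {
    msg <- c(msg, "gammaStar and deltaStar must have identical dimensions")
  }
  if (is.null(msg)) TRUE else msg
})

#' GraphIBModel: trained information-bottleneck graph classifier
#'
#' Holds the hyperparameter list, all trainable weights (subgraph-generator
#' network, GIN encoder, bilinear-pooling projection, classifier head), the
#' training seed and the per-epoch training history.
#'
#' @slot hyper list of hyperparameters (see [defaultHyperparams()]).
#' @slot params list of weight matrices/vectors per module.
#' @slot seed integer RNG seed the model was trained with.
#' @slot history data.frame of per-epoch losses and validation accuracy.
#' @export
setClass("GraphIBModel",
  representation(hyper = "list", params = "list", seed = "integer",
                 history = "data.frame")
)

#' SubtypeSolution: density-peaks clustering result
#'
#' Per-subject local densities `rho`, distances to the nearest
#' higher-density subject `delta`, prominences `gamma = rho * delta`,
#' the selected cluster centers and the cluster assignment.
#'
#' @slot rho numeric local densities.
#' @slot delta numeric distance to nearest higher-density point.
#' @slot gamma numeric prominence scores.
#' @slot centers integer indices of cluster centers.
#' @slot assignment integer cluster labels in 1..C.
#' @slot dc numeric, the density cutoff used.
#' @export
setClass("SubtypeSolution",
  representation(rho = "numeric", delta = "numeric", gamma = "numeric",
                 centers = "integer", assignment = "integer", dc = "numeric")
)

setValidity("SubtypeSolution", function(object) {
  msg <- NULL
  nn <- length(object@rho)
  if (length(object@delta) != nn || length(object@gamma) != nn ||
      length(object@assignment) != nn) {
    msg <- c(msg, "rho, delta, gamma, assignment must have equal length")
  }
  if (length(object@centers) < 1L) msg <- c(msg, "at least one center required")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ConnectomeSet", function(object) {
  cat("ConnectomeSet with", ncol(object), "subjects,",
      object@nRois, "ROIs (", nrow(object), "edges )\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  sites:", paste(names(table(cd$site)), collapse = ", "), "\n")
  cat("  cases/controls:", sum(cd$diagnosis == 1), "/", sum(cd$diagnosis == 0), "\n")
})

setMethod("show", "BrainGraph", function(object) {
  n <- nrow(object@adjacency)
  cat("BrainGraph:", n, "nodes,", sum(object@adjacency) / 2,
      "undirected edges, label =", object@label, "\n")
})

setMethod("show", "CombatModel", function(object) {
  cat("CombatModel:", length(object@siteLevels), "sites,",
      length(object@grandMean), "edges,",
      length(object@covariateNames), "covariates\n")
})

setMethod("show", "SubtypeSolution", function(object) {
  cat("SubtypeSolution:", length(object@centers), "subtypes, sizes:",
      paste(tabulate(object@assignment), collapse = "/"), "\n")
})
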