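## Connectivity matrices, phenotype tables, graph construction.

#' Fisher r-to-z transform
#'
#' Variance-stabilizing transform of Pearson correlations,
#' `z = atanh(r)`. Correlations are clamped to `|r| <= 1 - clamp` first so
#' that degenerate (perfectly correlated) inputs map to a large finite value
#' rather than infinity.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @param clamp Clamping margin (default `1e-7`).
#' @return Fisher-z value(s), same shape as `r`.
#' @export
#' @examples
#' fisherZ(0.5)   # 0.5 * log(3)
fisherZ <- function(r, clamp = 1e-7) {
  if (!all(is.finite(r))) stop("fisherZ: non-finite input", call. = FALSE)
  r <- pmin(pmax(r, -1 + clamp), 1 - clamp)
  atanh(r)
}

#' Functional connectivity from ROI time series
#'
#' Computes the Fisher-z Pearson correlation between every pair of ROI mean
#' time courses. Rows of `ts` are ROIs, columns are time points. The
#' diagonal is set to zero by convention (the z-transform of a self
#' correlation is infinite).
#'
#' @param ts `n x T` matrix of ROI time series (`T >= 3`).
#' @param roiLabels Optional ROI labels.
#' @return `n x n` symmetric Fisher-z matrix with zero diagonal.
#' @export
computeFC <- function(ts, roiLabels = NULL) {
  stopifnot(is.matrix(ts))
  if (ncol(ts) < 3L) stop("computeFC: need at least 3 time points", call. = FALSE)
  .checkFinite(ts, "time series")
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    lab <- if (is.null(roiLabels)) bad else roiLabels[bad]
    stop("computeFC: constant time series for ROI(s): ",
         paste(lab, collapse = ", "), call. = FALSE)
  }
  R <- stats::cor(t(ts))
  Z <- fisherZ(R)
  diag(Z) <- 0
  Z <- (Z + t(Z)) / 2
  if (!is.null(roiLabels)) dimnames(Z) <- list(roiLabels, roiLabels)
  Z
}

#' Binarize a connectivity matrix by top-percentile absolute strength
#'
#' Keeps the `round(fraction * n*(n-1)/2)` undirected edges with the
#' largest absolute connectivity (ties broken deterministically by
#' descending absolute value, then ascending row, then ascending column)
#' and sets everything else to zero. Rounding is half-away-from-zero.
#'
#' @param fc `n x n` symmetric connectivity matrix.
#' @param fraction Proportion of edges to keep, in `(0, 1]` (default 0.2).
#' @return `n x n` binary symmetric adjacency matrix with zero diagonal.
#' @export
#' @examples
#' # a 116-ROI matrix at the default fraction keeps exactly 1334 edges
binarizeTopK <- function(fc, fraction = 0.2) {
  stopifnot(is.matrix(fc), nrow(fc) == ncol(fc))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("binarizeTopK: fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(fc)
  pairs <- utPairs(n)
  v <- abs(fc[pairs])
  m <- as.integer(.roundHalfUp(fraction * n * (n - 1) / 2))
  ord <- order(-v, pairs[, 1L], pairs[, 2L])
  keep <- ord[seq_len(m)]
  A <- matrix(0, n, n)
  A[pairs[keep, , drop = FALSE]] <- 1
  A + t(A)
}

#' Build a brain graph from a connectivity matrix
#'
#' Pairs a top-percentile binary adjacency with node features: row k of the
#' feature matrix is ROI k's connectivity profile (the matrix row itself,
#' diagonal zero).
#'
#' @param fc `n x n` symmetric Fisher-z connectivity matrix.
#' @param label Diagnostic label (0/1, NA allowed).
#' @param fraction Edge-retention fraction passed to [binarizeTopK()].
#' @return A [BrainGraph-class] object.
#' @export
buildGraph <- function(fc, label = NA_real_, fraction = 0.2) {
  A <- binarizeTopK(fc, fraction)
  X <- fc
  diag(X) <- 0
  new("BrainGraph", adjacency = A, features = X, label = as.numeric(label))
}

#' Construct a ConnectomeSet from matrices and a phenotype table
#'
#' @param matrices List of `n x n` symmetric Fisher-z matrices (zero
#'   diagonal), one per subject, aligned with the rows of `phenotype`.
#' @param phenotype data.frame with columns `subject_id`, `site`,
#'   `diagnosis` and any covariate / symptom columns.
#' @param roiLabels Optional character vector of ROI names.
#' @return A [ConnectomeSet-class].
#' @export
ConnectomeSet <- function(matrices, phenotype, roiLabels = NULL) {
  stopifnot(is.list(matrices), length(matrices) == nrow(phenotype))
  n <- nrow(matrices[[1L]])
  for (k in seq_along(matrices)) {
    M <- matrices[[k]]
    if (!is.matrix(M) || nrow(M) != n || ncol(M) != n) {
      stop("matrix ", k, " is not ", n, "x", n, call. = FALSE)
    }
    if (max(abs(M - t(M))) > 1e-10) stop("matrix ", k, " is not symmetric", call. = FALSE)
    if (any(diag(M) != 0)) stop("matrix ", k, " must have a zero diagonal", call. = FALSE)
    .checkFinite(M[upper.tri(M)], paste("matrix", k))
  }
  if (is.null(roiLabels)) roiLabels <- paste0("ROI", seq_len(n))
  edges <- vapply(matrices, matToEdges, numeric(n * (n - 1) / 2))
  pairs <- utPairs(n)
  rd <- S4Vectors::DataFrame(
    roi1 = pairs[, 1L], roi2 = pairs[, 2L],
    edge = paste(roiLabels[pairs[, 1L]], roiLabels[pairs[, 2L]], sep = "--")
  )
  colnames(edges) <- phenotype$subject_id
  rownames(edges) <- rd$edge
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(fcz = edges),
    rowData = rd,
    colData = S4Vectors::DataFrame(phenotype, row.names = phenotype$subject_id)
  )
  new("ConnectomeSet", se, nRois = as.integer(n), roiLabels = roiLabels)
}

#' @describeIn ConnectomeSet Number of ROIs.
#' @param x A `ConnectomeSet`.
#' @export
nRois <- function(x) x@nRois

#' @describeIn ConnectomeSet ROI labels.
#' @export
roiLabels <- function(x) x@roiLabels

#' Materialize one subject's full connectivity matrix
#'
#' @param x A [ConnectomeSet-class].
#' @param subject Subject index or `subject_id`.
#' @return `n x n` symmetric matrix, zero diagonal.
#' @export
fcMatrix <- function(x, subject) {
  e <- SummarizedExperiment::assay(x, "fcz")[, subject]
  M <- edgesToMat(e, x@nRois)
  dimnames(M) <- list(x@roiLabels, x@roiLabels)
  M
}

#' Build brain graphs for every subject of a ConnectomeSet
#'
#' @param x A [ConnectomeSet-class] (or a plain edges-by-subjects matrix,
#'   in which case `nRoisOverride` and `labels` must be given).
#' @param fraction Edge-retention fraction (default 0.2).
#' @param labels Optional label vector overriding `diagnosis`.
#' @param nRoisOverride ROI count when `x` is a plain matrix.
#' @return List of [BrainGraph-class] objects.
#' @export
buildGraphs <- function(x, fraction = 0.2, labels = NULL, nRoisOverride = NULL) {
  if (is(x, "ConnectomeSet")) {
    edges <- SummarizedExperiment::assay(x, "fcz")
    n <- x@nRois
    if (is.null(labels)) labels <- SummarizedExperiment::colData(x)$diagnosis
  } else {
    edges <- x
    n <- nRoisOverride
    stopifnot(!is.null(n), !is.null(labels))
  }
  lapply(seq_len(ncol(edges)), function(s) {
    buildGraph(edgesToMat(edges[, s], n), label = labels[s], fraction = fraction)
  })
}

#' Read / write a square connectivity matrix as delimited text
#'
#' Plain headerless delimited text; the on-disk representation of a
#' connectivity matrix or an exported edge mask.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return `readFCMatrix`: a numeric matrix.
#' @export
readFCMatrix <- function(path, delim = "\t") {
  M <- as.matrix(utils::read.table(path, sep = delim, header = FALSE))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) stop("readFCMatrix: matrix is not square", call. = FALSE)
  M
}

#' @rdname readFCMatrix
#' @param M Matrix to write.
#' @export
writeFCMatrix <- function(M, path, delim = "\t") {
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = delim, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with a header row; `subject_id`, `site` and `diagnosis` are required,
#' empty fields are read as missing.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readPhenotype <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  req <- c("subject_id", "site", "diagnosis")
  miss <- setdiff(req, colnames(ph))
  if (length(miss)) {
    stop("readPhenotype: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ph$subject_id)) {
    stop("readPhenotype: duplicated subject_id", call. = FALSE)
  }
  ph
}
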