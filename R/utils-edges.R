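## Upper-triangle edge indexing used throughout the package.
## Edge order is the column-major order of upper.tri(), so edge vectors,
## assay rows and mask flattenings are always mutually consistent.

#' Upper-triangle ROI pairs
#'
#' Enumerates the undirected ROI pairs (i < j) of an `n`-node network in the
#' canonical order used for edge vectors throughout the package (column-major
#' upper triangle, the order of `M[upper.tri(M)]`).
#'
#' @param n Number of ROIs.
#' @return Integer matrix with columns `i`, `j` and one row per edge.
#' @export
#' @examples
#' utPairs(4)
utPairs <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Flatten a symmetric matrix to its upper-triangle edge vector
#'
#' @param M Symmetric square matrix.
#' @return Numeric vector in the canonical edge order of [utPairs()].
#' @export
matToEdges <- function(M) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  M[upper.tri(M)]
}

#' Rebuild a symmetric zero-diagonal matrix from an edge vector
#'
#' @param e Edge vector in canonical order.
#' @param n Number of ROIs.
#' @return `n` x `n` symmetric matrix with zero diagonal.
#' @export
edgesToMat <- function(e, n) {
  stopifnot(length(e) == n * (n - 1) / 2)
  M <- matrix(0, n, n)
  M[upper.tri(M)] <- e
  M + t(M)
}

## round-half-away-from-zero; base round() uses banker's rounding
.roundHalfUp <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.relu <- function(x) {
  x[x < 0] <- 0
  x
}

## Stable binary cross-entropy from probabilities
.bce <- function(y, p, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

.checkFinite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}
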