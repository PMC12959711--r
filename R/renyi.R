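## Matrix-based Renyi alpha-order entropy and mutual information.
## Information quantities are estimated from the eigenspectrum of
## trace-normalized RBF Gram matrices of mini-batch embeddings -- no density
## estimation and no auxiliary estimator network. Entropies are in bits.

#' Estimate an RBF kernel width from embeddings
#'
#' For each sample, the mean Euclidean distance to its `k` nearest other
#' samples is computed; the kernel width is the mean of these per-sample
#' means. A single global width keeps the Gram matrix a valid positive
#' semi-definite kernel matrix.
#'
#' @param Z Numeric matrix, samples x dimensions.
#' @param k Number of nearest neighbours (default 10, capped at N - 1).
#' @return Positive scalar kernel width.
#' @export
estimateSigma <- function(Z, k = 10) {
  Z <- as.matrix(Z)
  N <- nrow(Z)
  if (N < 2L) stop("estimateSigma: need at least 2 samples", call. = FALSE)
  k <- min(k, N - 1L)
  D <- as.matrix(stats::dist(Z))
  perSample <- vapply(seq_len(N), function(i) {
    di <- sort(D[i, -i])[seq_len(k)]
    mean(di)
  }, numeric(1))
  sigma <- mean(perSample)
  if (sigma <= 0) stop("estimateSigma: all points identical (sigma = 0)",
                       call. = FALSE)
  sigma
}

#' RBF Gram matrix
#'
#' `K_ij = exp(-||z_i - z_j||^2 / (2 sigma^2))`; unit diagonal, symmetric,
#' positive semi-definite.
#'
#' @param Z Numeric matrix, samples x dimensions.
#' @param sigma Positive kernel width.
#' @return N x N Gram matrix.
#' @export
rbfGram <- function(Z, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("rbfGram: sigma must be a positive scalar", call. = FALSE)
  }
  Z <- as.matrix(Z)
  D2 <- as.matrix(stats::dist(Z))^2
  K <- exp(-D2 / (2 * sigma^2))
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- NULL
  K
}

#' Matrix-based Renyi alpha-order entropy
#'
#' `H_alpha(A) = (1/(1-alpha)) log2 sum_i lambda_i(A)^alpha` with
#' `A = K / tr(K)`; eigenvalues are clamped at a small floor before
#' powering. Returned in bits; bounded by `log2(N)`.
#'
#' @param K Symmetric PSD Gram matrix.
#' @param alpha Entropy order in `(0,1) U (1, Inf)`.
#' @return Entropy in bits.
#' @export
renyiEntropy <- function(K, alpha = 1.01) {
  .checkAlpha(alpha)
  K <- as.matrix(K)
  tk <- sum(diag(K))
  if (tk <= 0) stop("renyiEntropy: trace must be positive", call. = FALSE)
  lam <- eigen((K + t(K)) / (2 * tk), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  ## eigenvalues below numerical rank are exact zeros of the spectrum
  lam[lam < max(lam) * length(lam) * 1e-14] <- 0
  s <- sum(lam^alpha)
  (1 / (1 - alpha)) * log2(s)
}

.checkAlpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha == 1) {
    stop("alpha must be in (0,1) or (1,Inf); alpha = 1 exactly is undefined ",
         "(use a value near 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Joint Renyi entropy of two Gram matrices
#'
#' `H_alpha((A o B) / tr(A o B))` where `o` is the Hadamard product of the
#' trace-normalized inputs (the normalization cancels, so the entropy of the
#' raw Hadamard product is identical).
#'
#' @param K1,K2 Gram matrices of equal size.
#' @param alpha Entropy order.
#' @return Joint entropy in bits.
#' @export
jointEntropy <- function(K1, K2, alpha = 1.01) {
  K1 <- as.matrix(K1)
  K2 <- as.matrix(K2)
  if (!identical(dim(K1), dim(K2))) {
    stop("jointEntropy: dimension mismatch", call. = FALSE)
  }
  renyiEntropy(K1 * K2, alpha)
}

#' Matrix-based Renyi mutual information between two embedding sets
#'
#' `MI = H(Z1) + H(Z2) - H(Z1, Z2)` on RBF Gram matrices with data-derived
#' kernel widths (unless given). Symmetric and non-negative up to numerical
#' tolerance.
#'
#' @param Z1,Z2 Matrices with the same number of rows (samples).
#' @param alpha Entropy order (default 1.01, near-Shannon).
#' @param k Neighbour count for [estimateSigma()].
#' @param sigma1,sigma2 Optional fixed kernel widths.
#' @return Mutual information in bits.
#' @export
mutualInformation <- function(Z1, Z2, alpha = 1.01, k = 10,
                              sigma1 = NULL, sigma2 = NULL) {
  Z1 <- as.matrix(Z1)
  Z2 <- as.matrix(Z2)
  if (nrow(Z1) != nrow(Z2)) stop("mutualInformation: sample count mismatch",
                                 call. = FALSE)
  if (nrow(Z1) < 2L) stop("mutualInformation: need at least 2 samples",
                          call. = FALSE)
  K1 <- .gramOrOnes(Z1, sigma1, k)
  K2 <- .gramOrOnes(Z2, sigma2, k)
  renyiEntropy(K1, alpha) + renyiEntropy(K2, alpha) -
    jointEntropy(K1, K2, alpha)
}

## Degenerate embeddings (all rows identical) have sigma undefined; their
## Gram matrix is the all-ones matrix regardless of width.
.gramOrOnes <- function(Z, sigma, k) {
  N <- nrow(Z)
  if (is.null(sigma)) {
    spread <- max(abs(sweep(Z, 2L, Z[1L, ], "-")))
    if (spread == 0) return(matrix(1, N, N))
    sigma <- estimateSigma(Z, k)
  }
  rbfGram(Z, sigma)
}

## Gradient of H_alpha(K/tr(K)) w.r.t. K (symmetric K).
.entropyGradK <- function(K, alpha, floor = 1e-12) {
  tk <- sum(diag(K))
  A <- (K + t(K)) / (2 * tk)
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, floor)
  s <- sum(lam^alpha)
  GA <- (alpha / ((1 - alpha) * s * log(2))) *
    (eg$vectors %*% (lam^(alpha - 1) * t(eg$vectors)))
  G <- GA / tk
  diag(G) <- diag(G) - sum(GA * A) / tk
  G
}

## Gradient of MI(Zsub, Z) w.r.t. Zsub with fixed kernel widths and fixed Z.
## Used by the training loop; checked against finite differences in tests.
.miGradZsub <- function(Zsub, Z, alpha = 1.01, sigmaSub, sigma) {
  Ksub <- rbfGram(Zsub, sigmaSub)
  K <- rbfGram(Z, sigma)
  ## dMI/dKsub = dH(Ksub)/dKsub - dH(Ksub o K)/dKsub
  M <- .entropyGradK(Ksub, alpha) - .entropyGradK(Ksub * K, alpha) * K
  W <- 2 * M * Ksub / sigmaSub^2
  diag(W) <- 0
  W %*% Zsub - rowSums(W) * Zsub
}
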