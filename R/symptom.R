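## Brain-symptom association: PCA-reduced graph embeddings predicting
## symptom scores with leave-one-out ridge regression, permutation
## significance and FDR control across symptom dimensions.

#' PCA reduction to a target explained variance
#'
#' Mean-centered principal components; retains the smallest number of
#' components whose cumulative explained variance reaches the target.
#'
#' @param embeddings Subjects x dimensions matrix.
#' @param varianceTarget Cumulative explained-variance target (default
#'   0.95).
#' @return List with `scores` (subjects x k), `rotation`, `center`,
#'   `explained` (per-component proportions) and `k`.
#' @export
pcaReduce <- function(embeddings, varianceTarget = 0.95) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L) stop("pcaReduce: need >= 2 subjects", call. = FALSE)
  pc <- stats::prcomp(embeddings, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(expl) >= varianceTarget - 1e-12)[1L]
  if (is.na(k)) k <- length(expl)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       rotation = pc$rotation[, seq_len(k), drop = FALSE],
       center = pc$center, explained = expl[seq_len(k)], k = k)
}

## Ridge fit with unpenalized intercept: center X and y, solve
## (X'X + lambda I) beta = X'y on the centered data.
.ridgeFit <- function(X, y, lambda) {
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm)
  beta <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, y - ym))
  list(beta = beta, xm = xm, ym = ym)
}

.ridgePredict <- function(fit, X) {
  drop(sweep(X, 2L, fit$xm) %*% fit$beta) + fit$ym
}

#' Closed-form leave-one-out predictions for fixed-penalty ridge
#'
#' The algebraic LOO identity for a penalized linear smoother:
#' `y_i - yhat_loo_i = (y_i - yhat_i) / (1 - h_ii)` with `h_ii` the
#' leverages of the (intercept-augmented) ridge hat matrix. Used as the
#' independent check of the explicit refitting loop.
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param lambda Ridge penalty.
#' @return Vector of LOO predictions.
#' @export
ridgeLOOShortcut <- function(X, y, lambda) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xa <- cbind(1, X)
  P <- diag(c(0, rep(lambda, ncol(X))))
  Hi <- Xa %*% solve(crossprod(Xa) + P, t(Xa))
  yhat <- drop(Hi %*% y)
  h <- diag(Hi)
  y - (y - yhat) / (1 - h)
}

#' Leave-one-out ridge regression with inner penalty selection
#'
#' For each left-out subject, the ridge penalty is chosen by inner 5-fold
#' cross-validation on the remaining subjects over a log-spaced grid in
#' `[1e-5, 1e5]` (strictly leakage-free), the model is refit on those
#' subjects, and the held-out subject is predicted. Performance is
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` (which can be
#' negative for predictions worse than the mean) and the mean absolute
#' error.
#'
#' @param X Predictor matrix (e.g. PCA-reduced embeddings).
#' @param y Symptom scores (non-constant).
#' @param lambdaGrid Candidate penalties (default 21 log-spaced points in
#'   `[1e-5, 1e5]`).
#' @param innerK Inner folds for penalty selection (default 5).
#' @param fixedLambda Optional fixed penalty (skips the inner CV).
#' @param seed RNG seed for the inner fold split.
#' @return List with `predictions`, `r2`, `mae`, `lambdaPath`.
#' @export
looRidge <- function(X, y, lambdaGrid = 10^seq(-5, 5, length.out = 21),
                     innerK = 5, fixedLambda = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, n >= 3L)
  if (stats::sd(y) == 0) stop("looRidge: constant response", call. = FALSE)
  set.seed(seed)
  preds <- numeric(n)
  lambdaPath <- numeric(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    if (is.null(fixedLambda)) {
      fold <- rep_len(sample.int(innerK), nrow(Xi))
      cvErr <- vapply(lambdaGrid, function(lm) {
        errs <- vapply(seq_len(innerK), function(f) {
          tr <- fold != f
          if (sum(tr) < 2L || all(!tr)) return(NA_real_)
          fit <- .ridgeFit(Xi[tr, , drop = FALSE], yi[tr], lm)
          mean((yi[!tr] - .ridgePredict(fit, Xi[!tr, , drop = FALSE]))^2)
        }, numeric(1))
        mean(errs, na.rm = TRUE)
      }, numeric(1))
      lam <- lambdaGrid[which.min(cvErr)]
    } else {
      lam <- fixedLambda
    }
    lambdaPath[i] <- lam
    fit <- .ridgeFit(Xi, yi, lam)
    preds[i] <- .ridgePredict(fit, X[i, , drop = FALSE])
  }
  r2 <- 1 - sum((y - preds)^2) / sum((y - mean(y))^2)
  list(predictions = preds, r2 = r2, mae = mean(abs(y - preds)),
       lambdaPath = lambdaPath)
}

#' Permutation significance of cross-validated r-squared
#'
#' Builds a null r2 distribution by permuting the response and re-running
#' the identical leave-one-out pipeline; `p = (1 + #[null >= observed]) /
#' (P + 1)`. With a matrix response (columns = symptom dimensions) the
#' p-values are BH-FDR adjusted across dimensions.
#'
#' @param X Predictor matrix.
#' @param y Vector or matrix of symptom scores.
#' @param P Permutations (default 1000).
#' @param seed RNG seed.
#' @param ... Passed to [looRidge()] (e.g. `fixedLambda` for speed).
#' @return data.frame with `dimension`, `r2`, `mae`, `p` and `fdr_q`.
#' @export
permutationR2 <- function(X, y, P = 1000, seed = 1L, ...) {
  if (P < 1L) stop("permutationR2: P must be >= 1", call. = FALSE)
  y <- as.matrix(y)
  out <- lapply(seq_len(ncol(y)), function(j) {
    obs <- looRidge(X, y[, j], seed = seed, ...)
    set.seed(seed + j)
    nullR2 <- vapply(seq_len(P), function(p) {
      looRidge(X, y[sample.int(nrow(y)), j], seed = seed, ...)$r2
    }, numeric(1))
    dimName <- if (is.null(colnames(y))) paste0("y", j) else colnames(y)[j]
    data.frame(dimension = dimName,
               r2 = obs$r2, mae = obs$mae,
               p = (1 + sum(nullR2 >= obs$r2)) / (P + 1))
  })
  res <- do.call(rbind, out)
  res$fdr_q <- stats::p.adjust(res$p, method = "BH")
  res
}
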