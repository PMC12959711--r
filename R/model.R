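## The trainable model: an amortized subgraph generator producing
## concrete-relaxed edge masks, a GIN encoder over the masked (weighted)
## adjacency, bilinear second-order pooling to a fixed-length graph
## embedding, a logistic classifier head, and the composite
## information-bottleneck loss
##   L = L_clf + lambda1 * MI(Z_sub, Z) + lambda2 * L_sps + lambda3 * L_ent.
## All gradients are hand-derived and verified against finite differences.

#' Hyperparameter profiles
#'
#' `"desk"` is the default profile used by the synthetic benchmark: a
#' compact encoder (1 GIN layer, 30 hidden units, 30-dimensional pooling
#' projection, identity-regime initialization, no dropout, learning rate
#' 3e-3, weight decay 1e-2) that trains in about a minute per 200-subject
#' fold on one CPU; early stopping keeps the best-validation checkpoint
#' with patience equal to the epoch cap, because a desk-scale validation
#' split is too small for aggressive stopping. `"full"` is the full-scale
#' profile for 116-ROI cohorts: 5 GIN layers, 2-layer MLPs, 128 hidden
#' units, batch 64, 350 epochs, dropout 0.5, temperature 1, loss weights
#' `lambda1 = 1e-4`, `lambda2 = 1e-5`, `lambda3 = 1e-4`, learning rate
#' 1e-3, weight decay 5e-4, patience 10.
#'
#' @param profile `"desk"` or `"full"`.
#' @param ... Named overrides of individual fields.
#' @return Named list of hyperparameters.
#' @export
defaultHyperparams <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  h <- list(
    gnn_layers = 1L, mlp_layers = 2L, hidden_dim = 30L, sopool_dim = 30L,
    gen_hidden = 16L, temperature = 1, lambda1 = 1e-4, lambda2 = 1e-5,
    lambda3 = 1e-4, learning_rate = 3e-3, batch_size = 32L,
    weight_decay = 1e-2, dropout = 0, epochs = 100L, alpha = 1.01,
    patience = 100L, val_fraction = 0.15, graph_norm = FALSE,
    init = "identity"
  )
  if (profile == "full") {
    h$gnn_layers <- 5L
    h$hidden_dim <- 128L
    h$sopool_dim <- 32L
    h$gen_hidden <- 64L
    h$batch_size <- 64L
    h$epochs <- 350L
    h$learning_rate <- 1e-3
    h$weight_decay <- 5e-4
    h$dropout <- 0.5
    h$graph_norm <- TRUE
    h$init <- "he"
    h$patience <- 10L
    h$val_fraction <- 0.1
  }
  over <- list(...)
  stopifnot(all(names(over) %in% names(h)))
  h[names(over)] <- over
  stopifnot(h$temperature > 0, h$dropout >= 0, h$dropout < 1,
            h$mlp_layers == 2L)
  h
}

#' Initialize model parameters
#'
#' Two schemes, selected by `hyper$init`. `"he"` is the conventional
#' He-style random initialization with zero biases. `"identity"`
#' initializes the GIN MLPs and the pooling projection near the identity
#' map with a positive first-layer bias, so that each unit starts in its
#' affine regime and the initial graph embedding is approximately the
#' second-order statistics of the connectivity profiles themselves; early
#' training then refines an interpretable quadratic readout rather than a
#' random one, which on mean-shift connectivity signals converges far
#' faster. The classifier head starts at zero (initial prediction 0.5) in
#' both schemes.
#'
#' @param nNodes Number of graph nodes (ROIs).
#' @param hyper Hyperparameter list from [defaultHyperparams()].
#' @param seed RNG seed.
#' @return A [GraphIBModel-class] with untrained parameters.
#' @export
initModel <- function(nNodes, hyper = defaultHyperparams(), seed = 1L) {
  set.seed(seed)
  n <- as.integer(nNodes)
  f <- hyper$hidden_dim
  fp <- hyper$sopool_dim
  dg <- hyper$gen_hidden
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  scheme <- hyper$init %||% "he"
  idm <- function(nin, nout, noise = 0.02) {
    diag(1, nin, nout) + matrix(rnorm(nin * nout, 0, noise), nin, nout)
  }
  params <- list(
    gen = list(W1 = he(2 * n, dg), b1 = numeric(dg),
               w2 = rnorm(dg, sd = sqrt(2 / dg)), b2 = 0),
    gin = lapply(seq_len(hyper$gnn_layers), function(k) {
      fin <- if (k == 1L) n else f
      if (scheme == "identity") {
        list(eps = 0, W1 = idm(fin, f), b1 = rep(1, f),
             W2 = idm(f, f), b2 = numeric(f))
      } else {
        list(eps = 0, W1 = he(fin, f), b1 = numeric(f),
             W2 = he(f, f), b2 = numeric(f))
      }
    }),
    sopool = list(W = if (scheme == "identity") idm(f, fp) else he(f, fp)),
    head = list(w = numeric(fp * fp), b = 0)
  )
  new("GraphIBModel", hyper = hyper, params = params, seed = as.integer(seed),
      history = data.frame())
}

#' Trainable-parameter counts per module
#'
#' Counts weights and biases of every learnable layer; parameter-free
#' operations (activations, dropout, pooling, flattening) contribute zero,
#' so the pooling module counts only its projection matrix.
#'
#' @param model A [GraphIBModel-class].
#' @return Named list with per-module counts and `total`.
#' @export
paramCount <- function(model) {
  p <- model@params
  cnt <- function(x) sum(vapply(x, length, integer(1)))
  gen <- cnt(p$gen)
  gin <- sum(vapply(p$gin, cnt, numeric(1)))
  sop <- length(p$sopool$W)
  head <- cnt(p$head)
  list(generator = gen, encoder = gin, pooling = sop, head = head,
       total = gen + gin + sop + head)
}

setMethod("show", "GraphIBModel", function(object) {
  pc <- paramCount(object)
  cat("GraphIBModel (", object@hyper$gnn_layers, "GIN layers, hidden",
      object@hyper$hidden_dim, ", pooling dim", object@hyper$sopool_dim, ")\n")
  cat("  parameters: generator", pc$generator, "| encoder", pc$encoder,
      "| pooling", pc$pooling, "| head", pc$head, "| total", pc$total, "\n")
  if (nrow(object@history)) {
    cat("  trained", nrow(object@history), "epochs; best val acc",
        sprintf("%.3f", max(object@history$val_acc, na.rm = TRUE)), "\n")
  }
})

#' Edge logits of the subgraph generator
#'
#' The generator is an amortized network shared across subjects: for every
#' existing edge (i, j) it scores the concatenated node-feature pair and
#' symmetrizes over the two orders,
#' `omega_ij = (g([x_i, x_j]) + g([x_j, x_i])) / 2`.
#' Amortization (rather than free per-subject parameters) is what makes
#' subject-specific masks available for unseen test subjects.
#'
#' @param graph A [BrainGraph-class].
#' @param params Model parameter list (element `gen`).
#' @return List with `edges` (m x 2 index matrix of the graph's
#'   upper-triangle edges) and `omega` (length-m logits).
#' @export
edgeLogits <- function(graph, params) {
  A <- graph@adjacency
  X <- graph@features
  pairs <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2L], pairs[, 1L]), , drop = FALSE]
  g <- params$gen
  U1 <- cbind(X[pairs[, 1L], , drop = FALSE], X[pairs[, 2L], , drop = FALSE])
  U2 <- cbind(X[pairs[, 2L], , drop = FALSE], X[pairs[, 1L], , drop = FALSE])
  fwd <- function(U) {
    A1 <- sweep(U %*% g$W1, 2L, g$b1, "+")
    drop(.relu(A1) %*% g$w2) + g$b2
  }
  list(edges = pairs, omega = 0.5 * (fwd(U1) + fwd(U2)))
}

#' Sample a concrete-relaxed edge mask
#'
#' Binary-concrete relaxation: with uniform noise `eps` per undirected edge,
#' `e = sigmoid((log eps - log(1 - eps) + omega) / tau)`. One shared draw
#' per undirected edge keeps the mask symmetric. With `noise = NULL`
#' (evaluation mode) `eps = 0.5` is used, giving the deterministic mask
#' `e = sigmoid(omega / tau)`.
#'
#' @param omega Edge logits.
#' @param tau Positive temperature.
#' @param noise Optional uniform(0,1) draws, one per edge; `NULL` for the
#'   deterministic evaluation mask.
#' @return Mask values in (0, 1), one per edge.
#' @export
sampleMask <- function(omega, tau = 1, noise = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("sampleMask: tau must be positive", call. = FALSE)
  }
  if (is.null(noise)) noise <- rep(0.5, length(omega))
  stopifnot(length(noise) == length(omega), all(noise > 0 & noise < 1))
  .sigmoid((log(noise) - log(1 - noise) + omega) / tau)
}

#' Apply an edge mask to a graph
#'
#' Returns the weighted adjacency `A' = A * M` of the explanation subgraph;
#' node features are unchanged.
#'
#' @param graph A [BrainGraph-class].
#' @param mask Either an n x n symmetric mask matrix or a per-edge vector
#'   aligned with `edgeLogits()$edges`.
#' @param edges Edge index matrix when `mask` is a vector.
#' @return Weighted adjacency matrix `A'`.
#' @export
applyMask <- function(graph, mask, edges = NULL) {
  A <- graph@adjacency
  if (is.matrix(mask)) return(A * mask)
  stopifnot(!is.null(edges), nrow(edges) == length(mask))
  Aw <- matrix(0, nrow(A), ncol(A))
  Aw[edges] <- mask
  Aw <- Aw + t(Aw)
  A * Aw
}

#' GIN encoder forward pass
#'
#' Iterates `h_v <- MLP((1 + eps) h_v + sum_u A'_uv h_u)` with a 2-layer
#' ReLU MLP per layer; the neighbour sum is weighted by the (possibly
#' masked) adjacency so the edge mask influences the encoder gradient.
#' Dropout (inverted, train mode only) follows each layer's MLP.
#'
#' @param Aw Weighted adjacency (n x n, symmetric).
#' @param X Node features (n x f0).
#' @param ginParams List of per-layer parameter lists.
#' @param dropout Dropout rate; only used when `dropMasks` is supplied or
#'   `train = TRUE`.
#' @param train Logical; draw dropout masks from the RNG when TRUE.
#' @param cache Logical; return intermediates for backprop.
#' @param graphNorm Logical; per-channel RMS scaling of each layer's
#'   output across the graph's nodes. This is a batch-independent analogue
#'   of the batch normalization customary in GIN implementations: it keeps
#'   activations bounded across depth without running statistics, while
#'   preserving permutation equivariance and per-channel mean structure.
#' @return Node embedding matrix `H` (n x f), or a list with `H` and
#'   `cache` when `cache = TRUE`.
#' @export
ginEncode <- function(Aw, X, ginParams, dropout = 0, train = FALSE,
                      cache = FALSE, graphNorm = TRUE) {
  H <- X
  caches <- vector("list", length(ginParams))
  for (k in seq_along(ginParams)) {
    pk <- ginParams[[k]]
    S <- (1 + pk$eps) * H + Aw %*% H
    Z1 <- sweep(S %*% pk$W1, 2L, pk$b1, "+")
    R1 <- .relu(Z1)
    Z2 <- sweep(R1 %*% pk$W2, 2L, pk$b2, "+")
    Hk <- .relu(Z2)
    gn <- NULL
    if (graphNorm) {
      sdc <- sqrt(colMeans(Hk^2) + 1e-5)
      Hk <- sweep(Hk, 2L, sdc, "/")
      gn <- list(sd = sdc, Hn = Hk)
    }
    dm <- NULL
    if (train && dropout > 0) {
      dm <- matrix(rbinom(length(Hk), 1L, 1 - dropout), nrow(Hk)) / (1 - dropout)
      Hk <- Hk * dm
    }
    if (cache) caches[[k]] <- list(Hin = H, S = S, Z1 = Z1, R1 = R1,
                                   Z2 = Z2, gn = gn, drop = dm)
    H <- Hk
    if (any(!is.finite(H))) stop("ginEncode: non-finite activation",
                                 call. = FALSE)
  }
  if (cache) list(H = H, cache = caches) else H
}

#' Bilinear-mapping second-order pooling
#'
#' Graph-level readout `h_G = flatten(W' H' H W)`: the f' x f' projected
#' feature covariance, flattened to a length-f'^2 vector. Invariant to any
#' node permutation of `H`.
#'
#' @param H Node embeddings (n x f).
#' @param W Projection matrix (f x f').
#' @return Numeric vector of length `f'^2`.
#' @export
sopoolBimap <- function(H, W) {
  if (ncol(H) != nrow(W)) stop("sopoolBimap: shape mismatch", call. = FALSE)
  HW <- H %*% W
  as.numeric(crossprod(HW))
}

#' Classifier head
#'
#' Single-logit affine map plus sigmoid over the graph embedding.
#'
#' @param hG Graph embedding vector.
#' @param headParams List with weight vector `w` and bias `b`.
#' @return Probability in (0, 1).
#' @export
classifyEmbedding <- function(hG, headParams) {
  .sigmoid(sum(headParams$w * hG) + headParams$b)
}

## ---- forward/backward over a batch -------------------------------------

## Forward pass for one graph. Train mode samples mask noise and dropout
## from the current RNG stream; eval mode is deterministic (eps = 0.5 mask,
## no dropout). The full-graph pass (Z) always runs without dropout.
.forwardGraph <- function(graph, params, hyper, train = FALSE) {
  el <- edgeLogits(graph, params)
  noise <- if (train) runif(length(el$omega), 1e-6, 1 - 1e-6) else NULL
  e <- sampleMask(el$omega, hyper$temperature, noise)
  Aw <- applyMask(graph, e, el$edges)
  enc <- ginEncode(Aw, graph@features, params$gin, hyper$dropout,
                   train = train, cache = TRUE,
                   graphNorm = isTRUE(hyper$graph_norm))
  zsub <- sopoolBimap(enc$H, params$sopool$W)
  Hfull <- ginEncode(graph@adjacency, graph@features, params$gin,
                     graphNorm = isTRUE(hyper$graph_norm))
  z <- sopoolBimap(Hfull, params$sopool$W)
  yhat <- classifyEmbedding(zsub, params$head)
  list(edges = el$edges, omega = el$omega, noise = noise, e = e, Aw = Aw,
       enc = enc, zsub = zsub, z = z, yhat = yhat)
}

## Batch forward: returns per-graph states plus the composite loss pieces.
.forwardBatch <- function(graphs, params, hyper, train = FALSE) {
  states <- lapply(graphs, .forwardGraph, params = params, hyper = hyper,
                   train = train)
  y <- vapply(graphs, function(g) g@label, numeric(1))
  yhat <- vapply(states, `[[`, numeric(1), "yhat")
  Zsub <- do.call(rbind, lapply(states, `[[`, "zsub"))
  Z <- do.call(rbind, lapply(states, `[[`, "z"))
  loss <- compositeLoss(yhat, y, lapply(states, `[[`, "e"), Zsub, Z, hyper)
  list(states = states, y = y, yhat = yhat, Zsub = Zsub, Z = Z, loss = loss)
}

#' Composite information-bottleneck loss
#'
#' `L = L_clf + lambda1 L_mask + lambda2 L_sps + lambda3 L_ent` where
#' `L_clf` is the mean binary cross-entropy, `L_mask` the matrix-based
#' Renyi mutual information between subgraph and full-graph embeddings,
#' `L_sps` the batch-mean sum of mask values over upper-triangle edges
#' (compactness) and `L_ent` the batch-mean sum of per-edge binary
#' entropies in nats (discreteness; `0 log 0 := 0`).
#'
#' @param yhat Predicted probabilities.
#' @param y Labels (0/1).
#' @param masks List of per-edge mask vectors (upper-triangle edges only).
#' @param Zsub,Z Batch embedding matrices (subjects x f'^2).
#' @param hyper Hyperparameter list (uses `lambda1..3`, `alpha`).
#' @param sigmaSub,sigma Optional fixed kernel widths for the MI term.
#' @return List with `total`, `clf`, `mask`, `sps`, `ent`.
#' @export
compositeLoss <- function(yhat, y, masks, Zsub, Z, hyper,
                          sigmaSub = NULL, sigma = NULL) {
  if (length(y) < 2L) stop("compositeLoss: batch size must be >= 2",
                           call. = FALSE)
  lclf <- .bce(y, yhat)
  lsps <- mean(vapply(masks, sum, numeric(1)))
  lent <- mean(vapply(masks, function(m) {
    m <- pmin(pmax(m, 1e-12), 1 - 1e-12)
    -sum(m * log(m) + (1 - m) * log(1 - m))
  }, numeric(1)))
  lmask <- mutualInformation(Zsub, Z, hyper$alpha,
                             sigma1 = sigmaSub, sigma2 = sigma)
  total <- lclf + hyper$lambda1 * lmask + hyper$lambda2 * lsps +
    hyper$lambda3 * lent
  list(total = total, clf = lclf, mask = lmask, sps = lsps, ent = lent)
}

## Zero-filled gradient container shaped like params.
.zeroLike <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

## Analytic backprop of the composite loss over one batch.
## MI gradient flows into Z_sub only; the full-graph embedding Z and the
## kernel widths are treated as constants (stop-gradient).
.backwardBatch <- function(fwd, params, hyper) {
  B <- length(fwd$states)
  grads <- .zeroLike(params)
  ## MI gradient w.r.t. Zsub rows (skip degenerate all-equal batches)
  spreadS <- max(abs(sweep(fwd$Zsub, 2L, fwd$Zsub[1L, ], "-")))
  spreadZ <- max(abs(sweep(fwd$Z, 2L, fwd$Z[1L, ], "-")))
  if (spreadS > 0 && spreadZ > 0) {
    sS <- estimateSigma(fwd$Zsub)
    sZ <- estimateSigma(fwd$Z)
    Gmi <- .miGradZsub(fwd$Zsub, fwd$Z, hyper$alpha, sS, sZ)
  } else {
    Gmi <- matrix(0, B, ncol(fwd$Zsub))
  }

  for (b in seq_len(B)) {
    st <- fwd$states[[b]]
    dlogit <- (st$yhat - fwd$y[b]) / B
    grads$head$w <- grads$head$w + dlogit * st$zsub
    grads$head$b <- grads$head$b + dlogit
    dz <- dlogit * params$head$w + hyper$lambda1 * Gmi[b, ]

    ## pooling backward
    fp <- hyper$sopool_dim
    dP <- matrix(dz, fp, fp)
    H <- st$enc$H
    G <- crossprod(H)
    W <- params$sopool$W
    grads$sopool$W <- grads$sopool$W + G %*% W %*% (dP + t(dP))
    dG <- W %*% dP %*% t(W)
    dH <- H %*% (dG + t(dG))

    ## GIN backward (masked-adjacency pass only; Z path is stop-gradient)
    L <- length(params$gin)
    dAw <- matrix(0, nrow(st$Aw), ncol(st$Aw))
    for (k in rev(seq_len(L))) {
      ck <- st$enc$cache[[k]]
      pk <- params$gin[[k]]
      if (!is.null(ck$drop)) dH <- dH * ck$drop
      if (!is.null(ck$gn)) {
        Hn <- ck$gn$Hn
        dH <- dH - sweep(Hn, 2L, colMeans(dH * Hn), "*")
        dH <- sweep(dH, 2L, ck$gn$sd, "/")
      }
      dZ2 <- dH * (ck$Z2 > 0)
      grads$gin[[k]]$W2 <- grads$gin[[k]]$W2 + crossprod(ck$R1, dZ2)
      grads$gin[[k]]$b2 <- grads$gin[[k]]$b2 + colSums(dZ2)
      dR1 <- dZ2 %*% t(pk$W2)
      dZ1 <- dR1 * (ck$Z1 > 0)
      grads$gin[[k]]$W1 <- grads$gin[[k]]$W1 + crossprod(ck$S, dZ1)
      grads$gin[[k]]$b1 <- grads$gin[[k]]$b1 + colSums(dZ1)
      dS <- dZ1 %*% t(pk$W1)
      grads$gin[[k]]$eps <- grads$gin[[k]]$eps + sum(dS * ck$Hin)
      dAw <- dAw + tcrossprod(dS, ck$Hin)
      dH <- (1 + pk$eps) * dS + st$Aw %*% dS
    }

    ## mask backward: A' entries at (i,j) and (j,i) share one mask value
    de <- dAw[st$edges] + dAw[st$edges[, c(2L, 1L), drop = FALSE]]
    m <- pmin(pmax(st$e, 1e-12), 1 - 1e-12)
    de <- de + hyper$lambda2 / B + (hyper$lambda3 / B) * log((1 - m) / m)
    domega <- de * st$e * (1 - st$e) / hyper$temperature

    ## generator backward through both argument orders
    X <- fwd$states[[b]]$enc$cache[[1L]]$Hin
    g <- params$gen
    for (ord in 1:2) {
      idx <- if (ord == 1L) st$edges else st$edges[, c(2L, 1L), drop = FALSE]
      U <- cbind(X[idx[, 1L], , drop = FALSE], X[idx[, 2L], , drop = FALSE])
      A1 <- sweep(U %*% g$W1, 2L, g$b1, "+")
      R <- .relu(A1)
      dgv <- 0.5 * domega
      grads$gen$w2 <- grads$gen$w2 + drop(crossprod(R, dgv))
      grads$gen$b2 <- grads$gen$b2 + sum(dgv)
      dA1 <- (dgv %o% g$w2) * (A1 > 0)
      grads$gen$W1 <- grads$gen$W1 + crossprod(U, dA1)
      grads$gen$b1 <- grads$gen$b1 + colSums(dA1)
    }
  }
  grads
}
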