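test_that("edge logits are symmetric functions of node-feature pairs", {
  g <- randomGraphs(1, n = 8, seed = 3)[[1]]
  ## give three nodes identical features
  g@features[2, ] <- g@features[1, ]
  g@features[, 2] <- g@features[, 1]
  m <- initModel(8, tinyHyper(), seed = 1)
  el <- edgeLogits(g, m@params)
  ## logits exist only on upper-triangle adjacency entries
  expect_true(all(g@adjacency[el$edges] == 1))
  expect_equal(nrow(el$edges), sum(g@adjacency) / 2)
  ## determinism
  el2 <- edgeLogits(g, m@params)
  expect_identical(el$omega, el2$omega)
  ## edges sharing identical endpoint features get equal logits
  feats <- g@features
  key <- apply(el$edges, 1, function(e) {
    paste(sort(c(paste(round(feats[e[1], ], 10), collapse = ","),
                 paste(round(feats[e[2], ], 10), collapse = ","))),
          collapse = "|")
  })
  dup <- split(el$omega, key)
  for (grp in dup) expect_lt(diff(range(grp)), 1e-12)
})

test_that("concrete mask sampling follows the sigmoid law", {
  set.seed(99)
  for (omega in c(-2, 0, 2)) {
    draws <- sampleMask(rep(omega, 1e4), tau = 1, noise = runif(1e4))
    expect_equal(mean(draws > 0.5), plogis(omega), tolerance = 0.02)
  }
  ## deterministic mask at eps = 0.5 and the low-temperature limit
  expect_equal(sampleMask(2, tau = 1), plogis(2))
  expect_gt(sampleMask(1, tau = 0.01), 1 - 1e-10)
  expect_lt(sampleMask(-1, tau = 0.01), 1e-10)
  expect_error(sampleMask(0, tau = 0), "tau")
})

test_that("mask application is elementwise on the adjacency", {
  g <- randomGraphs(1, n = 6, seed = 5)[[1]]
  n <- 6
  ## identity mask: subgraph equals graph
  expect_equal(applyMask(g, matrix(1, n, n)), g@adjacency)
  ## zero mask: empty weighted adjacency, encoder still runs
  A0 <- applyMask(g, matrix(0, n, n))
  expect_true(all(A0 == 0))
  m <- initModel(n, tinyHyper(), seed = 2)
  H <- ginEncode(A0, g@features, m@params$gin)
  expect_true(all(is.finite(H)))
  ## arbitrary mask: A'_ij = A_ij * M_ij
  set.seed(5)
  Mv <- matrix(runif(n * n), n)
  Mv <- (Mv + t(Mv)) / 2
  expect_equal(applyMask(g, Mv), g@adjacency * Mv)
})

test_that("GIN encoding is permutation equivariant", {
  g <- randomGraphs(1, n = 9, seed = 7)[[1]]
  m <- initModel(9, tinyHyper(), seed = 3)
  H <- ginEncode(g@adjacency, g@features, m@params$gin)
  set.seed(8)
  for (i in 1:5) {
    perm <- sample.int(9)
    Hp <- ginEncode(g@adjacency[perm, perm], g@features[perm, ],
                    m@params$gin)
    expect_equal(Hp, H[perm, ], tolerance = 1e-5)
  }
})

test_that("a 1-layer GIN on a 3-node path matches hand computation", {
  ## path 1-2-3 with weights; identity-like MLP (no norm) for hand checking
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.5
  A[2, 3] <- A[3, 2] <- 0.25
  X <- diag(3)
  gin <- list(list(eps = 0.1, W1 = diag(3), b1 = rep(0, 3),
                   W2 = diag(3), b2 = rep(0, 3)))
  H <- ginEncode(A, X, gin, graphNorm = FALSE)
  ## S = (1.1) X + A X, then two identity layers with relu (all entries >= 0)
  S <- 1.1 * X + A %*% X
  expect_equal(H, pmax(S, 0), tolerance = 1e-12)
})

test_that("second-order pooling is node-permutation invariant and exact", {
  set.seed(21)
  H <- matrix(rnorm(7 * 4), 7, 4)
  W <- matrix(rnorm(4 * 2), 4, 2)
  z <- sopoolBimap(H, W)
  expect_equal(length(z), 4)
  ## invariance under row permutation, bitwise-equal sums up to fp error
  expect_equal(sopoolBimap(H[sample(7), ], W), z, tolerance = 1e-12)
  ## identity-column projection picks the leading block of H'H
  W2 <- diag(4)[, 1:2]
  G <- crossprod(H)
  expect_equal(matrix(sopoolBimap(H, W2), 2, 2), G[1:2, 1:2],
               tolerance = 1e-12)
  ## brute-force sum of outer products
  Gb <- Reduce(`+`, lapply(seq_len(7), function(i) tcrossprod(H[i, ])))
  expect_equal(matrix(z, 2, 2), t(W) %*% Gb %*% W, tolerance = 1e-10)
  ## PSD of the pooled matrix
  expect_true(min(eigen(matrix(z, 2, 2), symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-10)
  expect_error(sopoolBimap(H, matrix(0, 3, 2)), "shape")
})

test_that("classifier head is a logistic map", {
  expect_equal(classifyEmbedding(rnorm(5), list(w = rep(0, 5), b = 0)), 0.5)
  h <- c(1, -2, 3)
  hp <- list(w = c(0.5, 0.1, -0.2), b = 0.3)
  expect_equal(classifyEmbedding(h, hp),
               plogis(sum(h * hp$w) + 0.3), tolerance = 1e-12)
  ## monotone in the logit
  expect_gt(classifyEmbedding(h * 2, hp), 0)
})

test_that("composite loss components match plug-in values", {
  hyp <- tinyHyper(lambda1 = 0, lambda2 = 1, lambda3 = 1)
  Z <- matrix(rnorm(8), 4, 2)
  Zs <- matrix(rnorm(8), 4, 2)
  mEdges <- 10
  masks <- replicate(4, rep(0.5, mEdges), simplify = FALSE)
  l <- compositeLoss(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 1, 0), masks, Zs, Z, hyp)
  expect_equal(l$ent, mEdges * log(2), tolerance = 1e-12)
  expect_equal(l$sps, 0.5 * mEdges, tolerance = 1e-12)
  expect_equal(l$clf, log(2), tolerance = 1e-12)
  ## binary masks have zero entropy (0 log 0 := 0)
  masksBin <- replicate(4, rep(c(0, 1), 5), simplify = FALSE)
  lb <- compositeLoss(c(1, 0, 1, 0) * 0.999 + 5e-4, c(1, 0, 1, 0),
                      masksBin, Zs, Z, hyp)
  expect_equal(lb$ent, 0, tolerance = 1e-8)
  expect_lt(lb$clf, 0.01)
  expect_error(compositeLoss(0.5, 1, masks[1], Zs[1, , drop = FALSE],
                             Z[1, , drop = FALSE], hyp), "batch")
})

test_that("whole-model prediction is invariant to node relabeling", {
  g <- randomGraphs(1, n = 10, seed = 11)[[1]]
  m <- initModel(10, tinyHyper(), seed = 4)
  m@params$head$w <- rnorm(9, sd = 0.5)
  p0 <- predictProb(m, list(g))
  z0 <- graphEmbeddings(m, list(g))$Zsub
  set.seed(12)
  for (i in 1:20) {
    ## relabel nodes: each node keeps its feature descriptor vector
    perm <- sample.int(10)
    gp <- new("BrainGraph", adjacency = g@adjacency[perm, perm],
              features = g@features[perm, , drop = FALSE], label = g@label)
    expect_equal(predictProb(m, list(gp)), p0, tolerance = 1e-5)
    expect_equal(graphEmbeddings(m, list(gp))$Zsub, z0, tolerance = 1e-5)
  }
})

test_that("parameter counts cover exactly the learnable layers", {
  h <- tinyHyper()
  m <- initModel(7, h, seed = 1)
  pc <- paramCount(m)
  n <- 7; f <- h$hidden_dim; fp <- h$sopool_dim; dg <- h$gen_hidden
  expect_equal(pc$generator, 2 * n * dg + dg + dg + 1)
  expect_equal(pc$encoder,
               (1 + n * f + f + f * f + f) + (1 + f * f + f + f * f + f))
  ## pooling contributes only the f x f' projection entries
  expect_equal(pc$pooling, f * fp)
  expect_equal(pc$head, fp^2 + 1)
  expect_equal(pc$total, pc$generator + pc$encoder + pc$pooling + pc$head)
})

test_that("analytic gradients of the full loss match finite differences", {
  graphs <- randomGraphs(6, n = 8, seed = 42)
  h <- tinyHyper(lambda1 = 0.05, lambda2 = 0.01, lambda3 = 0.01)
  m <- initModel(8, h, seed = 3)
  params <- m@params
  params$head$w <- rnorm(9, sd = 0.02)
  fwd <- connectomeIB:::.forwardBatch(graphs, params, h, train = FALSE)
  gr <- connectomeIB:::.backwardBatch(fwd, params, h)
  ## fixed widths so the finite difference follows the same stop-gradient
  ## path as the analytic computation for the clf/sps/ent terms; MI term
  ## checked separately in the entropy tests, so drop it here
  h0 <- h
  h0$lambda1 <- 0
  fwd0 <- connectomeIB:::.forwardBatch(graphs, params, h0, train = FALSE)
  gr0 <- connectomeIB:::.backwardBatch(fwd0, params, h0)
  lossOf <- function(p) {
    connectomeIB:::.forwardBatch(graphs, p, h0, train = FALSE)$loss$total
  }
  eps <- 1e-5
  spots <- list(
    list(get = function(g) g$gen$W1[3, 2],
         set = function(p, d) { p$gen$W1[3, 2] <- p$gen$W1[3, 2] + d; p }),
    list(get = function(g) g$gin[[1]]$eps,
         set = function(p, d) { p$gin[[1]]$eps <- p$gin[[1]]$eps + d; p }),
    list(get = function(g) g$gin[[2]]$W2[1, 1],
         set = function(p, d) { p$gin[[2]]$W2[1, 1] <- p$gin[[2]]$W2[1, 1] + d; p }),
    list(get = function(g) g$sopool$W[4, 2],
         set = function(p, d) { p$sopool$W[4, 2] <- p$sopool$W[4, 2] + d; p }),
    list(get = function(g) g$head$w[5],
         set = function(p, d) { p$head$w[5] <- p$head$w[5] + d; p })
  )
  for (sp in spots) {
    num <- (lossOf(sp$set(params, eps)) - lossOf(sp$set(params, -eps))) /
      (2 * eps)
    expect_equal(sp$get(gr0), num, tolerance = 1e-3)
  }
})
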