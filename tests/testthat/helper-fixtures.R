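## Shared fixtures, generated in code.

## small random symmetric Fisher-z style matrix with zero diagonal
randomFC <- function(n, seed = 1, sd = 0.5) {
  set.seed(seed)
  M <- matrix(rnorm(n * n, 0, sd), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  M
}

## list of random BrainGraphs with alternating labels
randomGraphs <- function(nGraphs, n = 8, fraction = 0.4, seed = 1) {
  lapply(seq_len(nGraphs), function(i) {
    buildGraph(randomFC(n, seed = seed + i), label = i %% 2,
               fraction = fraction)
  })
}

## a tiny hyperparameter profile for fast model tests
tinyHyper <- function(...) {
  defaultHyperparams(hidden_dim = 6L, sopool_dim = 3L, gen_hidden = 4L,
                     gnn_layers = 2L, dropout = 0, batch_size = 8L,
                     epochs = 3L, ...)
}

## two-site edge data with a planted additive offset on site B
twoSiteEdges <- function(nEdges = 60, nPer = 40, offset = 2, mult = 1,
                         seed = 7) {
  set.seed(seed)
  template <- rnorm(nEdges, 0.2, 0.3)
  siteA <- template + matrix(rnorm(nEdges * nPer, 0, 0.5), nEdges)
  siteB <- template + offset + mult * matrix(rnorm(nEdges * nPer, 0, 0.5), nEdges)
  list(edges = cbind(siteA, siteB),
       sites = rep(c("A", "B"), each = nPer),
       template = template)
}

## pseudo-embeddings whose correlation structure separates three groups:
## each group follows a distinct activation pattern plus small noise
patternedEmbeddings <- function(nPer, dims = 6, noise = 0.3, seed = 1) {
  set.seed(seed)
  centers <- matrix(1, 3, dims)
  for (k in 1:3) centers[k, (2 * k - 1):(2 * k)] <- 5
  emb <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rep(centers[k, ], each = nPer), nPer) +
      matrix(rnorm(nPer * dims, 0, noise), nPer)
  }))
  list(emb = emb, labels = rep(1:3, each = nPer))
}

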