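test_that("embedding distance matches the correlation oracle", {
  set.seed(6)
  E <- matrix(rnorm(40), 5, 8)
  d <- embeddingDistance(E)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(d[i, j], 1 - cor(E[i, ], E[j, ]), tolerance = 1e-12)
    }
  }
  ## identical and anti-correlated rows
  E2 <- rbind(E[1, ], E[1, ], -E[1, ])
  d2 <- embeddingDistance(E2)
  expect_equal(d2[1, 2], 0, tolerance = 1e-12)
  expect_equal(d2[1, 3], 2, tolerance = 1e-12)
  expect_error(embeddingDistance(rbind(E[1, ], rep(1, 8))), "constant.*2")
})

## independent pencil-and-paper CFDP on 4 points
test_that("cfdp reproduces a hand-computed 4-point solution", {
  ## points on a line at 0, 1, 5, 6; dc = 2
  x <- c(0, 1, 5, 6)
  d <- abs(outer(x, x, "-"))
  dc <- 2
  ## hand-computed Gaussian densities rho_i = sum_j exp(-(d/dc)^2), j != i
  rhoHand <- sapply(1:4, function(i) sum(exp(-(d[i, -i] / dc)^2)))
  sol <- cfdp(d, dc = dc, nCenters = 2)
  expect_equal(sol@rho, rhoHand, tolerance = 1e-12)
  ## inner subjects 2 and 3 are the density maxima (tied, index breaks the
  ## tie): subject 2 is the global maximum with delta = max d = 5; subject
  ## 3's nearest denser point is 2 (distance 4); the outer subjects sit
  ## next to their blob's peak at distance 1
  expect_equal(sol@delta, c(1, 5, 4, 1))
  expect_equal(sol@gamma, sol@rho * sol@delta)
  expect_equal(sort(sol@centers), c(2L, 3L))
  expect_equal(sol@assignment, c(1, 1, 2, 2))
})

test_that("cfdp recovers three well-separated blobs", {
  blobs <- simulateBlobs(50, seed = 42)
  d <- as.matrix(dist(blobs$points))
  sol <- cfdp(d, nCenters = 3)
  expect_gte(ari(sol@assignment, blobs$labels), 0.95)
  ## auto center count finds 3 as well
  solAuto <- cfdp(d, nCenters = "auto")
  expect_equal(length(solAuto@centers), 3L)
  ## single center: one cluster
  expect_true(all(cfdp(d, nCenters = 1)@assignment == 1L))
})

test_that("cfdp is invariant to input ordering", {
  blobs <- simulateBlobs(30, seed = 3)
  d <- as.matrix(dist(blobs$points))
  sol <- cfdp(d, nCenters = 3)
  set.seed(1)
  perm <- sample.int(nrow(d))
  solP <- cfdp(d[perm, perm], dc = sol@dc, nCenters = 3)
  expect_equal(ari(solP@assignment, sol@assignment[perm]), 1)
})

test_that("decision-graph contract holds on blob data", {
  blobs <- simulateBlobs(40, seed = 8)
  d <- as.matrix(dist(blobs$points))
  sol <- cfdp(d, nCenters = 3)
  ## centers have jointly high rho and delta
  expect_true(all(sol@rho[sol@centers] > median(sol@rho)))
  expect_true(all(sol@delta[sol@centers] > quantile(sol@delta, 0.9)))
  ## dense non-centers sit close to a denser point
  dense <- setdiff(which(sol@rho > quantile(sol@rho, 0.75)), sol@centers)
  expect_true(all(sol@delta[dense] < 0.5 * min(sol@delta[sol@centers])))
})

test_that("silhouette and Dunn match a brute-force 4-point oracle", {
  x <- c(0, 1, 5, 6)
  d <- abs(outer(x, x, "-"))
  q <- clusterQuality(d, c(1, 1, 2, 2))
  ## hand: s(1)=s(4)=(5.5-1)/5.5, s(2)=s(3)=(4.5-1)/4.5
  expect_equal(q$silhouette, (2 * 4.5 / 5.5 + 2 * 3.5 / 4.5) / 4,
               tolerance = 1e-12)
  expect_equal(q$dunn, 4 / 1)
  expect_error(clusterQuality(d, rep(1, 4)), "single cluster")
})

test_that("cluster quality is high for blobs and near zero for noise", {
  blobs <- simulateBlobs(40, seed = 10)
  d <- as.matrix(dist(blobs$points))
  q <- clusterQuality(d, blobs$labels)
  expect_gt(q$silhouette, 0.7)
  expect_gt(q$dunn, 1)
  set.seed(2)
  one <- matrix(rnorm(120), 60, 2)
  qr <- clusterQuality(as.matrix(dist(one)), sample(1:3, 60, TRUE))
  expect_lt(abs(qr$silhouette), 0.1)
})

test_that("quality sweep peaks at the planted cluster number", {
  blobs <- simulateBlobs(50, seed = 42)
  d <- as.matrix(dist(blobs$points))
  sw <- qualitySweep(d, Ks = 1:9)
  expect_true(is.na(sw$silhouette[1]))
  expect_equal(sw$K[which.max(sw$silhouette)], 3)
  expect_equal(sw$K[which.max(sw$dunn)], 3)
})

test_that("top edges follow the sort oracle with deterministic ties", {
  set.seed(12)
  M <- randomFC(10, 13)
  M[M != 0] <- abs(M[M != 0])
  sel <- topEdges(M, K = 5)
  pairs <- utPairs(10)
  v <- M[pairs]
  expect_equal(sort(v[sel], decreasing = TRUE), sort(v, decreasing = TRUE)[1:5])
  ## all-equal scores: smallest (row, col) pairs (1,2),(1,3),(1,4),(1,5)
  Me <- matrix(0.4, 6, 6)
  diag(Me) <- 0
  expect_equal(topEdges(Me, K = 4), c(1L, 2L, 4L, 7L))
  expect_error(topEdges(diag(6), K = 4), "fewer than K")
})

test_that("edge frequencies sum to K per subtype and match counting", {
  sets <- list(c(1, 2, 3), c(1, 2, 4), c(5, 6, 7), c(5, 6, 7))
  f <- edgeFrequency(c(1, 1, 2, 2), sets, nEdges = 8)
  expect_equal(rowSums(f), c(subtype1 = 3, subtype2 = 3))
  expect_equal(f[1, 1], 1, ignore_attr = TRUE)
  expect_equal(f[1, 3], 0.5, ignore_attr = TRUE)
  expect_equal(f[2, 5], 1, ignore_attr = TRUE)
  ## disjoint sets in one subtype: 0.5 each
  f2 <- edgeFrequency(c(1, 1), list(1:3, 4:6), nEdges = 6)
  expect_true(all(f2[1, ] == 0.5))
})

test_that("jaccard matches closed forms", {
  expect_equal(jaccardIndex(1:20, 1:20), 1)
  expect_equal(jaccardIndex(1:10, 11:20), 0)
  expect_equal(jaccardIndex(1:20, 11:30), 10 / 30)
  expect_error(jaccardIndex(integer(0), integer(0)), "empty")
})

test_that("ARI/NMI agree with closed-form contingency oracles", {
  ## 2x2 contingency (2,0;0,2): perfect agreement
  expect_equal(ari(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  ## hand-computed ARI for partition (1,1,2,2) vs (1,2,1,2):
  ## all pair counts: sum nij C2 = 0, ai C2 = 2, bj C2 = 2, n C2 = 6
  ## ARI = (0 - 4/6) / (2 - 4/6) = -0.5
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0, tolerance = 1e-12)
  ## ARI under random relabeling concentrates near zero
  set.seed(77)
  a <- rep(1:3, each = 40)
  vals <- replicate(1000, ari(a, sample(a)))
  expect_lt(abs(mean(vals)), 0.02)
  expect_true(all(nmi(a, a) == 1))
})

test_that("bootstrap stability is high for separated blobs, low for noise", {
  pe <- patternedEmbeddings(30, seed = 5)
  emb <- pe$emb
  bs <- bootstrapStability(emb, nCenters = 3, B = 60, seed = 2)
  expect_gte(mean(bs$ari), 0.9)
  expect_gte(mean(bs$nmi), 0.9)
  ## structureless cloud: stability near the random-assignment null
  set.seed(6)
  noise <- matrix(rnorm(80 * 5), 80)
  bn <- bootstrapStability(noise, nCenters = 3, B = 40, seed = 3)
  expect_lt(mean(bn$ari), 0.5)
})

test_that("bootstrap jaccard and edge frequencies track planted signatures", {
  pe <- patternedEmbeddings(20, seed = 9)
  emb <- pe$emb
  set.seed(9)
  ## subtype-specific top sets: group k prefers edges (10k+1)..(10k+5)
  sets <- lapply(seq_len(60), function(s) {
    base <- pe$labels[s] * 10 + (1:5)
    c(base, 60 + sample.int(30, 5))
  })
  bs <- bootstrapStability(emb, nCenters = 3, B = 40, seed = 4,
                           topSets = sets, nEdges = 100, K = 5)
  expect_gte(mean(bs$jaccard, na.rm = TRUE), 0.8)
  ## reference sets must be the planted preferred edges
  refEdges <- sort(unlist(bs$referenceSets))
  expect_true(all(c(11:15, 21:25, 31:35) %in% refEdges))
})

test_that("permutation null p-values follow the add-one rule and BH", {
  ## observed below every null draw: p = 1; above all: p = 1/(P+1)
  set.seed(14)
  assignment <- rep(1:2, each = 10)
  sets <- lapply(seq_len(20), function(s) {
    if (assignment[s] == 1) 1:5 else 6:10
  })
  pn <- permutationNull(assignment, sets, nEdges = 12, P = 199, seed = 3,
                        K = 5)
  ## perfectly subtype-specific edges: no permutation reaches observed f = 1
  expect_true(all(pn$edges[[1]]$p == 1 / 200))
  expect_true(all(pn$edges[[1]]$fdr_q <= 0.05))
  ## BH step-up oracle
  p <- c(0.01, 0.02, 0.03, 0.5)
  expect_equal(p.adjust(p, "BH") <= 0.05, c(TRUE, TRUE, TRUE, FALSE))
  ## observed ARI far above the permutation null
  pn2 <- permutationNull(assignment, sets, nEdges = 12, P = 99, seed = 5,
                         K = 5, observedAri = 0.9)
  expect_lte(pn2$ariP, 0.05)
  expect_gt(pn2$ariCohensD, 2)
})

test_that("group comparison matches exact rank-sum enumeration", {
  ## groups (1,2,3) vs (4,5,6): the most extreme of C(6,3)=20 splits
  res <- groupCompare(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2),
                      bootstrapB = 200)
  expect_equal(res$p, 2 * 1 / 20, tolerance = 1e-12)
  ## identical distributions: p = 1, d = 0
  res2 <- groupCompare(rep(c(1, 2, 3), 2), rep(1:2, each = 3),
                       bootstrapB = 200)
  expect_equal(res2$p, 1)
  expect_equal(res2$cohens_d, 0)
  ## 1-SD shift at large n: d near 1
  set.seed(20)
  x <- c(rnorm(400), rnorm(400, 1))
  res3 <- groupCompare(x, rep(1:2, each = 400), bootstrapB = 200)
  expect_equal(abs(res3$cohens_d), 1, tolerance = 0.1)
  expect_lt(res3$p, 1e-10)
})
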