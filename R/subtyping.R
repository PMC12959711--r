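## Density-peaks subtyping of graph embeddings: correlation distances,
## CFDP clustering with a decision graph, internal cluster quality,
## subtype edge signatures (per-subject top-K mask edges, selection
## frequencies), and bootstrap/permutation stability statistics.

#' Correlation distance between subject embeddings
#'
#' `d_ij = 1 - pearson(h_i, h_j)`, in `[0, 2]`, zero diagonal.
#'
#' @param embeddings Subjects x dimensions matrix.
#' @return Symmetric distance matrix.
#' @export
embeddingDistance <- function(embeddings) {
  embeddings <- as.matrix(embeddings)
  if (nrow(embeddings) < 2L) stop("embeddingDistance: need >= 2 subjects",
                                  call. = FALSE)
  sds <- apply(embeddings, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("embeddingDistance: constant embedding for subject(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(embeddings))
  diag(d) <- 0
  pmin(pmax((d + t(d)) / 2, 0), 2)
}

#' Density-peaks clustering (CFDP)
#'
#' Computes per-subject Gaussian local densities
#' `rho_i = sum_{j != i} exp(-(d_ij/d_c)^2)`, the distance `delta_i` to the
#' nearest higher-density subject (the global density maximum receives the
#' maximum pairwise distance), prominences `gamma = rho * delta`, selects
#' the `nCenters` subjects with largest `gamma` as cluster centers, and
#' assigns every remaining subject, in decreasing-density order, to the
#' cluster of its nearest higher-density neighbour.
#'
#' The cutoff `dc = "auto"` uses the standard neighbourhood heuristic: the
#' 2% quantile of the pairwise distances. `nCenters = "auto"` takes the
#' largest relative gap in the sorted prominence sequence; an explicit
#' center count is the reproducible default for confirmatory analyses.
#'
#' @param d Symmetric distance matrix.
#' @param dc Density cutoff, or `"auto"`.
#' @param nCenters Number of centers, or `"auto"`.
#' @param neighborFraction Target neighbour fraction for the auto cutoff.
#' @return A [SubtypeSolution-class].
#' @export
cfdp <- function(d, dc = "auto", nCenters = "auto",
                 neighborFraction = 0.02) {
  d <- as.matrix(d)
  N <- nrow(d)
  stopifnot(N >= 2L, ncol(d) == N)
  off <- d[upper.tri(d)]
  if (max(off) == 0) stop("cfdp: all points identical", call. = FALSE)
  if (identical(dc, "auto")) {
    dc <- stats::quantile(off, neighborFraction, names = FALSE)
    if (dc <= 0) dc <- min(off[off > 0])
  }
  stopifnot(is.numeric(dc), dc > 0)
  rho <- rowSums(exp(-(d / dc)^2)) - 1  # exclude self term
  ## order by decreasing density; index breaks ties deterministically
  ord <- order(-rho, seq_len(N))
  delta <- numeric(N)
  nn <- integer(N)
  delta[ord[1L]] <- max(d[ord[1L], ])
  nn[ord[1L]] <- ord[1L]
  for (r in 2:N) {
    i <- ord[r]
    higher <- ord[seq_len(r - 1L)]
    j <- higher[which.min(d[i, higher])]
    delta[i] <- d[i, j]
    nn[i] <- j
  }
  gamma <- rho * delta
  if (identical(nCenters, "auto")) {
    gs <- sort(gamma, decreasing = TRUE)
    gs <- pmax(gs, 1e-12)
    gaps <- gs[-length(gs)] / gs[-1L]
    cand <- which.max(gaps[seq_len(min(9L, length(gaps)))])
    nCenters <- cand
  }
  nCenters <- as.integer(nCenters)
  stopifnot(nCenters >= 1L, nCenters <= N)
  centers <- order(-gamma, seq_len(N))[seq_len(nCenters)]
  assignment <- integer(N)
  assignment[centers] <- seq_len(nCenters)
  if (assignment[ord[1L]] == 0L) {
    ## density maximum is itself no center: attach it to the nearest center
    assignment[ord[1L]] <- assignment[centers[which.min(d[ord[1L], centers])]]
  }
  for (r in seq_len(N)) {
    i <- ord[r]
    if (assignment[i] == 0L) assignment[i] <- assignment[nn[i]]
  }
  new("SubtypeSolution", rho = rho, delta = delta, gamma = gamma,
      centers = as.integer(centers), assignment = assignment,
      dc = as.numeric(dc))
}

#' Internal cluster quality: silhouette and Dunn index
#'
#' Mean silhouette width (singletons scored 0) and the Dunn index
#' (minimum between-cluster distance over maximum within-cluster
#' diameter). Undefined for a single cluster.
#'
#' @param d Symmetric distance matrix.
#' @param assignment Integer cluster labels.
#' @return List with `silhouette` and `dunn`.
#' @export
clusterQuality <- function(d, assignment) {
  d <- as.matrix(d)
  ks <- sort(unique(assignment))
  if (length(ks) < 2L) {
    stop("clusterQuality: undefined for a single cluster", call. = FALSE)
  }
  sil <- cluster::silhouette(assignment, dmatrix = d)
  silhouette <- mean(sil[, "sil_width"])
  minInter <- Inf
  maxIntra <- 0
  for (a in ks) {
    ia <- which(assignment == a)
    if (length(ia) > 1L) {
      maxIntra <- max(maxIntra, max(d[ia, ia]))
    }
    for (b in ks[ks > a]) {
      ib <- which(assignment == b)
      minInter <- min(minInter, min(d[ia, ib]))
    }
  }
  if (maxIntra == 0) maxIntra <- .Machine$double.eps
  list(silhouette = silhouette, dunn = minInter / maxIntra)
}

#' Cluster-quality sweep over candidate subtype counts
#'
#' Re-runs CFDP with `nCenters = K` for each candidate K and reports both
#' indices; K = 1 rows are reported as `NA` (undefined).
#'
#' @param d Symmetric distance matrix.
#' @param Ks Candidate center counts (default 1:9).
#' @param dc Density cutoff passed to [cfdp()].
#' @return data.frame with `K`, `silhouette`, `dunn`.
#' @export
qualitySweep <- function(d, Ks = 1:9, dc = "auto") {
  out <- lapply(Ks, function(K) {
    if (K < 2L) {
      return(data.frame(K = K, silhouette = NA_real_, dunn = NA_real_))
    }
    sol <- cfdp(d, dc = dc, nCenters = K)
    if (length(unique(sol@assignment)) < 2L) {
      return(data.frame(K = K, silhouette = NA_real_, dunn = NA_real_))
    }
    q <- clusterQuality(d, sol@assignment)
    data.frame(K = K, silhouette = q$silhouette, dunn = q$dunn)
  })
  do.call(rbind, out)
}

#' Per-subject top-K mask edges
#'
#' The K undirected edges with the largest mask values; ties broken by
#' ascending (row, column), so an all-equal mask selects the K
#' lexicographically smallest edges.
#'
#' @param mask n x n symmetric mask matrix (zero where no edge).
#' @param K Number of edges (default 20).
#' @return Integer vector of canonical edge ids (see [utPairs()]).
#' @export
topEdges <- function(mask, K = 20) {
  n <- nrow(mask)
  pairs <- utPairs(n)
  v <- mask[pairs]
  defined <- which(v > 0)
  if (length(defined) < K) {
    stop("topEdges: fewer than K edges with defined scores", call. = FALSE)
  }
  ord <- order(-v, pairs[, 1L], pairs[, 2L])
  ord[seq_len(K)]
}

#' Subtype edge-selection frequencies
#'
#' For each subtype c and edge e, the fraction of the subtype's subjects
#' whose top-K set contains e. Frequencies over a subtype sum to exactly K.
#'
#' @param assignment Integer subtype labels.
#' @param topSets List of per-subject edge-id vectors (from [topEdges()]).
#' @param nEdges Total number of edges in the common index space.
#' @return Matrix, subtypes x edges, of selection frequencies.
#' @export
edgeFrequency <- function(assignment, topSets, nEdges) {
  stopifnot(length(assignment) == length(topSets))
  ks <- sort(unique(assignment))
  freq <- matrix(0, length(ks), nEdges,
                 dimnames = list(paste0("subtype", ks), NULL))
  for (ci in seq_along(ks)) {
    members <- which(assignment == ks[ci])
    if (!length(members)) stop("edgeFrequency: empty subtype", call. = FALSE)
    counts <- tabulate(unlist(topSets[members]), nbins = nEdges)
    freq[ci, ] <- counts / length(members)
  }
  freq
}

#' Jaccard index of two edge sets
#'
#' @param setA,setB Vectors (not both empty).
#' @return `|A intersect B| / |A union B|`.
#' @export
jaccardIndex <- function(setA, setB) {
  u <- union(setA, setB)
  if (length(u) == 0L) stop("jaccardIndex: both sets empty", call. = FALSE)
  length(intersect(setA, setB)) / length(u)
}

#' Adjusted Rand index
#'
#' Chance-adjusted partition agreement (wrapper around
#' `mclust::adjustedRandIndex`).
#'
#' @param a,b Two label vectors of equal length.
#' @return ARI in `[-1, 1]`, 1 for identical partitions.
#' @export
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

#' Normalized mutual information between partitions
#'
#' Shannon mutual information of the label contingency, normalized by the
#' arithmetic mean of the marginal entropies; in `[0, 1]`.
#'
#' @param a,b Two label vectors of equal length.
#' @return NMI value.
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  N <- length(a)
  tab <- table(a, b)
  pij <- tab / N
  pi <- rowSums(pij)
  pj <- colSums(pij)
  ha <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  hb <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (ha == 0 && hb == 0) return(1)
  mi <- 0
  for (i in seq_along(pi)) {
    for (j in seq_along(pj)) {
      if (pij[i, j] > 0) {
        mi <- mi + pij[i, j] * log(pij[i, j] / (pi[i] * pj[j]))
      }
    }
  }
  as.numeric(mi / ((ha + hb) / 2))
}

## Greedy maximal-overlap matching of resampled subtypes to reference
## subtypes (no Hungarian solver needed at C ~ 3).
.matchSubtypes <- function(refMembers, bootMembers) {
  nr <- length(refMembers)
  nb <- length(bootMembers)
  ov <- matrix(0, nr, nb)
  for (i in seq_len(nr)) {
    for (j in seq_len(nb)) {
      ov[i, j] <- length(intersect(refMembers[[i]], bootMembers[[j]]))
    }
  }
  match <- rep(NA_integer_, nr)
  for (k in seq_len(min(nr, nb))) {
    best <- which(ov == max(ov), arr.ind = TRUE)[1L, ]
    match[best[1L]] <- best[2L]
    ov[best[1L], ] <- -1
    ov[, best[2L]] <- -1
  }
  match
}

#' Bootstrap stability of the subtype solution
#'
#' Resamples subjects with replacement, re-runs CFDP with the reference
#' hyperparameters (same cutoff and center count), and quantifies
#' agreement with the reference solution by ARI and NMI computed on the
#' unique sampled subjects (duplicates collapse to one vote). When
#' per-subject top-K edge sets are supplied, each resample's subtype-level
#' top-K sets are compared to the reference sets by the Jaccard index
#' after greedy maximal-overlap subtype matching, and per-edge bootstrap
#' selection frequencies are accumulated.
#'
#' @param embeddings Subjects x dimensions embedding matrix.
#' @param nCenters Number of subtypes of the reference solution.
#' @param B Bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param topSets Optional list of per-subject top-K edge-id vectors.
#' @param nEdges Edge-space size (required with `topSets`).
#' @param K Top-edge count (default 20).
#' @param dc Density cutoff (default `"auto"`, resolved once on the
#'   reference solution and then held fixed).
#' @return List with the reference solution, `ari`/`nmi` vectors and
#'   mean + 95% percentile CI summaries, per-subtype `jaccard` matrix and
#'   `edgeSelectionFreq` (when `topSets` given).
#' @export
bootstrapStability <- function(embeddings, nCenters, B = 1000, seed = 1L,
                               topSets = NULL, nEdges = NULL, K = 20,
                               dc = "auto") {
  if (B < 1L) stop("bootstrapStability: B must be >= 1", call. = FALSE)
  d <- embeddingDistance(embeddings)
  ref <- cfdp(d, dc = dc, nCenters = nCenters)
  dcFixed <- ref@dc
  N <- nrow(d)
  C <- nCenters
  refMembers <- split(seq_len(N), ref@assignment)
  refSets <- NULL
  if (!is.null(topSets)) {
    stopifnot(!is.null(nEdges), length(topSets) == N)
    refFreq <- edgeFrequency(ref@assignment, topSets, nEdges)
    refSets <- lapply(seq_len(C), function(ci) {
      order(-refFreq[ci, ], seq_len(nEdges))[seq_len(K)]
    })
    selCount <- matrix(0, C, nEdges)
  }
  set.seed(seed)
  ariV <- numeric(B)
  nmiV <- numeric(B)
  jac <- if (!is.null(topSets)) matrix(NA_real_, B, C) else NULL
  for (b in seq_len(B)) {
    idx <- sample.int(N, replace = TRUE)
    sol <- cfdp(d[idx, idx, drop = FALSE], dc = dcFixed, nCenters = C)
    u <- !duplicated(idx)
    ariV[b] <- ari(sol@assignment[u], ref@assignment[idx[u]])
    nmiV[b] <- nmi(sol@assignment[u], ref@assignment[idx[u]])
    if (!is.null(topSets)) {
      bootFreq <- edgeFrequency(sol@assignment, topSets[idx], nEdges)
      bootSets <- lapply(seq_len(C), function(ci) {
        order(-bootFreq[ci, ], seq_len(nEdges))[seq_len(K)]
      })
      bootMembers <- split(idx[u], sol@assignment[u])
      mt <- .matchSubtypes(refMembers, bootMembers)
      for (ci in seq_len(C)) {
        if (!is.na(mt[ci])) {
          jac[b, ci] <- jaccardIndex(refSets[[ci]], bootSets[[mt[ci]]])
          selCount[ci, bootSets[[mt[ci]]]] <-
            selCount[ci, bootSets[[mt[ci]]]] + 1
        }
      }
    }
  }
  summ <- function(x) c(mean = mean(x, na.rm = TRUE),
                        stats::quantile(x, c(0.025, 0.975), na.rm = TRUE))
  out <- list(reference = ref, ari = ariV, nmi = nmiV,
              ariSummary = summ(ariV), nmiSummary = summ(nmiV))
  if (!is.null(topSets)) {
    out$jaccard <- jac
    out$jaccardSummary <- t(apply(jac, 2L, summ))
    out$edgeSelectionFreq <- selCount / B
    out$referenceSets <- refSets
  }
  out
}

#' Permutation null for subtype edge signatures and clustering stability
#'
#' Permutes subtype labels across subjects and re-derives null edge
#' selection frequencies and a null ARI (permuted labels vs the observed
#' assignment, a size-matched random-assignment null). Empirical p-values
#' use the add-one rule `p = (1 + #[null >= observed]) / (P + 1)` and are
#' BH-adjusted over the tested family (the reference edges of every
#' subtype).
#'
#' @param assignment Observed subtype labels.
#' @param topSets Per-subject top-K edge-id vectors.
#' @param nEdges Edge-space size.
#' @param P Permutations (default 1000).
#' @param seed RNG seed.
#' @param K Top-edge count defining the reference sets.
#' @param observedAri Optional observed stability (e.g. mean bootstrap
#'   ARI) to test against the null ARI distribution.
#' @return List with per-subtype data.frames (`edge`, `observed`, `p`,
#'   `fdr_q`), the `nullAri` distribution, and `ariP`/`ariCohensD` when
#'   `observedAri` is given.
#' @export
permutationNull <- function(assignment, topSets, nEdges, P = 1000,
                            seed = 1L, K = 20, observedAri = NULL) {
  if (P < 1L) stop("permutationNull: P must be >= 1", call. = FALSE)
  set.seed(seed)
  obsFreq <- edgeFrequency(assignment, topSets, nEdges)
  C <- nrow(obsFreq)
  refSets <- lapply(seq_len(C), function(ci) {
    order(-obsFreq[ci, ], seq_len(nEdges))[seq_len(K)]
  })
  exceed <- lapply(seq_len(C), function(ci) numeric(K))
  nullAri <- numeric(P)
  for (p in seq_len(P)) {
    perm <- assignment[sample.int(length(assignment))]
    nullFreq <- edgeFrequency(perm, topSets, nEdges)
    for (ci in seq_len(C)) {
      ids <- refSets[[ci]]
      exceed[[ci]] <- exceed[[ci]] +
        (nullFreq[ci, ids] >= obsFreq[ci, ids])
    }
    nullAri[p] <- ari(perm, assignment)
  }
  perSubtype <- lapply(seq_len(C), function(ci) {
    pv <- (1 + exceed[[ci]]) / (P + 1)
    data.frame(edge = refSets[[ci]],
               observed = obsFreq[ci, refSets[[ci]]],
               p = pv, fdr_q = NA_real_)
  })
  allP <- unlist(lapply(perSubtype, `[[`, "p"))
  allQ <- stats::p.adjust(allP, method = "BH")
  k0 <- 0
  for (ci in seq_len(C)) {
    perSubtype[[ci]]$fdr_q <- allQ[k0 + seq_len(K)]
    k0 <- k0 + K
  }
  out <- list(edges = perSubtype, nullAri = nullAri)
  if (!is.null(observedAri)) {
    out$ariP <- (1 + sum(nullAri >= observedAri)) / (P + 1)
    out$ariCohensD <- (observedAri - mean(nullAri)) /
      max(stats::sd(nullAri), .Machine$double.eps)
  }
  out
}

#' Pairwise group comparison of symptom scores
#'
#' Two-sided Wilcoxon rank-sum tests for every pair of groups (exact for
#' small tie-free samples, normal approximation with tie correction
#' otherwise), pooled-SD Cohen's d with a percentile-bootstrap 95% CI, and
#' BH-FDR adjustment over the pairs.
#'
#' @param values Numeric scores.
#' @param groups Group labels.
#' @param bootstrapB Bootstrap replicates for the d CI.
#' @param seed RNG seed.
#' @return data.frame, one row per pair, with `p`, `cohens_d`, `ci_lo`,
#'   `ci_hi`, `fdr_q`.
#' @export
groupCompare <- function(values, groups, bootstrapB = 2000, seed = 1L) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (any(table(groups) < 2L)) stop("groupCompare: group with < 2 members",
                                    call. = FALSE)
  if (length(lv) < 2L) stop("groupCompare: need >= 2 groups", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (i in seq_along(lv)) {
    for (j in seq_along(lv)) {
      if (j <= i) next
      xi <- values[groups == lv[i]]
      xj <- values[groups == lv[j]]
      p <- suppressWarnings(stats::wilcox.test(xi, xj)$p.value)
      sp <- sqrt(((length(xi) - 1) * stats::var(xi) +
                    (length(xj) - 1) * stats::var(xj)) /
                   (length(xi) + length(xj) - 2))
      dval <- if (sp == 0) 0 else (mean(xi) - mean(xj)) / sp
      boots <- vapply(seq_len(bootstrapB), function(b) {
        bi <- sample(xi, replace = TRUE)
        bj <- sample(xj, replace = TRUE)
        spb <- sqrt(((length(bi) - 1) * stats::var(bi) +
                       (length(bj) - 1) * stats::var(bj)) /
                      (length(bi) + length(bj) - 2))
        if (spb == 0) 0 else (mean(bi) - mean(bj)) / spb
      }, numeric(1))
      ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = lv[i], group2 = lv[j], p = p, cohens_d = dval,
        ci_lo = ci[1L], ci_hi = ci[2L])
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$p, method = "BH")
  out
}
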