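## Synthetic multisite connectome benchmark with known ground truth:
## additive/multiplicative site effects, covariate effects, a planted
## case-control discriminative edge set, three planted patient subtypes
## with disjoint edge signatures, and subtype-linked symptom scores.
## Every other module of the package is testable against these datasets
## without access-restricted cohort downloads.

#' Benchmark simulation configuration
#'
#' Defaults define the desk-scale study conditions: 400 subjects (half
#' cases), 30 ROIs, 3 sites, 15 planted discriminative edges with a
#' Fisher-z case shift of 0.5 against a residual SD of 0.5 (per-edge
#' Cohen's d near 1), additive site effects with SD 0.3 and multiplicative
#' site scaling in [0.7, 1.4], three equal-size case subtypes with
#' disjoint 10-edge signatures shifted by 0.4, mild covariate effects, and
#' 7 symptom items linearly coupled to the subject's subtype-edge
#' strengths at signal-to-noise (variance ratio) 2.
#'
#' @param nSubjects,nRois,nSites Cohort dimensions.
#' @param caseFraction Fraction of cases (exactly enforced).
#' @param siteAdditiveSd SD of per-site-per-edge additive offsets.
#' @param siteMultRange Range of per-site residual scale factors.
#' @param nPlanted Number of planted discriminative edges.
#' @param effectSize Fisher-z case shift on planted edges.
#' @param noiseSd Residual SD of edge values.
#' @param nSubtypes Number of planted case subtypes.
#' @param subtypeEdgeCount Edges per subtype signature (disjoint sets).
#' @param subtypeEffect Fisher-z shift on a subtype's signature edges.
#' @param covariateEffects Named per-covariate slopes (applied through
#'   fixed per-edge loadings).
#' @param symptomItems Number of symptom dimensions.
#' @param symptomSnr Signal-to-noise variance ratio of symptom items.
#' @param seed Mandatory RNG seed.
#' @param timeseriesMode If TRUE, subjects are generated as multivariate
#'   normal ROI time series (length `timeseriesLength`) around the
#'   subject-specific covariance implied by the edge template, and FC is
#'   computed with [computeFC()].
#' @param timeseriesLength Time points in time-series mode.
#' @return Classed list `"SimConfig"`.
#' @export
simConfig <- function(nSubjects = 400, nRois = 30, nSites = 3,
                      caseFraction = 0.5, siteAdditiveSd = 0.3,
                      siteMultRange = c(0.7, 1.4), nPlanted = 15,
                      effectSize = 0.5, noiseSd = 0.5, nSubtypes = 3,
                      subtypeEdgeCount = 10, subtypeEffect = 0.4,
                      covariateEffects = c(age = 0.003, sex = 0.05,
                                           motion = 0.2),
                      symptomItems = 7, symptomSnr = 2, seed = 1L,
                      timeseriesMode = FALSE, timeseriesLength = 150) {
  cfg <- as.list(environment())
  stopifnot(is.numeric(seed), length(seed) == 1L)
  nEdges <- nRois * (nRois - 1) / 2
  if (nPlanted + nSubtypes * subtypeEdgeCount > nEdges) {
    stop("simConfig: planted + subtype edge sets exceed available edges",
         call. = FALSE)
  }
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a multisite benchmark dataset
#'
#' Per subject, edge values are drawn around a common Fisher-z template;
#' cases receive the planted discriminative shift, each case's subtype adds
#' its signature shift, covariates shift edges linearly through fixed
#' per-edge loadings, and each site adds its additive offset and scales the
#' residual noise multiplicatively. Symptom items (cases only) are linear
#' in the subject's mean signature-edge deviation plus noise at the
#' configured signal-to-noise ratio. All draws come from the seeded
#' generator, so equal seeds give bit-identical datasets.
#'
#' @param cfg A [simConfig()] object.
#' @return List with `set` (a [ConnectomeSet-class]) and `truth` (planted
#'   edge ids, subtype assignment, subtype edge sets, site parameters,
#'   symptom weights, template).
#' @export
simulateDataset <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$nRois
  N <- cfg$nSubjects
  E <- n * (n - 1) / 2

  template <- rnorm(E, mean = 0.25, sd = 0.2)
  allEdges <- sample.int(E)
  planted <- sort(allEdges[seq_len(cfg$nPlanted)])
  subtypeSets <- lapply(seq_len(cfg$nSubtypes), function(c) {
    sort(allEdges[cfg$nPlanted + (c - 1) * cfg$subtypeEdgeCount +
                    seq_len(cfg$subtypeEdgeCount)])
  })

  diagnosis <- rep_len(c(1, 0), N)[sample.int(N)]
  nCase <- sum(diagnosis == 1)
  subtype <- rep(NA_integer_, N)
  subtype[diagnosis == 1] <- rep_len(seq_len(cfg$nSubtypes), nCase)[
    sample.int(nCase)]
  site <- paste0("site", rep_len(seq_len(cfg$nSites), N)[sample.int(N)])
  siteLevels <- paste0("site", seq_len(cfg$nSites))

  age <- rnorm(N, 40, 12)
  sex <- rbinom(N, 1L, 0.5)
  motion <- abs(rnorm(N, 0.15, 0.05))
  covStd <- cbind(age = (age - mean(age)) / stats::sd(age),
                  sex = sex - mean(sex),
                  motion = (motion - mean(motion)) / stats::sd(motion))
  covNames <- names(cfg$covariateEffects)
  loadings <- matrix(rnorm(E * length(covNames)), E, length(covNames))

  gammaSite <- matrix(rnorm(cfg$nSites * E, 0, cfg$siteAdditiveSd),
                      cfg$nSites, E, dimnames = list(siteLevels, NULL))
  deltaSite <- stats::setNames(
    runif(cfg$nSites, cfg$siteMultRange[1L], cfg$siteMultRange[2L]),
    siteLevels)

  edges <- matrix(0, E, N)
  for (s in seq_len(N)) {
    si <- match(site[s], siteLevels)
    v <- template + gammaSite[si, ]
    for (ci in seq_along(covNames)) {
      v <- v + cfg$covariateEffects[[ci]] * covStd[s, covNames[ci]] *
        loadings[, ci]
    }
    if (diagnosis[s] == 1) {
      v[planted] <- v[planted] + cfg$effectSize
      v[subtypeSets[[subtype[s]]]] <- v[subtypeSets[[subtype[s]]]] +
        cfg$subtypeEffect
    }
    edges[, s] <- v + deltaSite[si] * rnorm(E, 0, cfg$noiseSd)
  }

  ## subtype-linked symptoms: linear in the subject's mean signature-edge
  ## deviation from the template, noise scaled to the target SNR
  weights <- runif(cfg$symptomItems, 0.5, 1.5)
  latent <- rep(NA_real_, N)
  for (s in which(diagnosis == 1)) {
    ids <- subtypeSets[[subtype[s]]]
    latent[s] <- mean(edges[ids, s] - template[ids])
  }
  symptoms <- matrix(NA_real_, N, cfg$symptomItems,
                     dimnames = list(NULL, paste0("sym", seq_len(cfg$symptomItems))))
  caseIdx <- which(diagnosis == 1)
  sdSig <- stats::sd(latent[caseIdx])
  for (k in seq_len(cfg$symptomItems)) {
    signal <- weights[k] * latent[caseIdx]
    noiseSd <- weights[k] * sdSig / sqrt(cfg$symptomSnr)
    symptoms[caseIdx, k] <- 2 + signal + rnorm(nCase, 0, noiseSd)
  }

  pheno <- data.frame(subject_id = sprintf("sub%04d", seq_len(N)),
                      site = site, diagnosis = diagnosis, age = age,
                      sex = sex, motion = motion, symptoms)

  if (cfg$timeseriesMode) {
    matrices <- lapply(seq_len(N), function(s) {
      R <- tanh(edgesToMat(edges[, s], n))  # target correlations
      C <- R
      diag(C) <- 1
      eg <- eigen(C, symmetric = TRUE)
      C <- eg$vectors %*% (pmax(eg$values, 0.05) * t(eg$vectors))
      Dh <- 1 / sqrt(diag(C))
      C <- C * tcrossprod(Dh)
      L <- chol(C)
      ts <- t(L) %*% matrix(rnorm(n * cfg$timeseriesLength), n)
      computeFC(ts)
    })
  } else {
    matrices <- lapply(seq_len(N), function(s) edgesToMat(edges[, s], n))
  }

  set <- ConnectomeSet(matrices, pheno)
  truth <- list(plantedEdges = planted, subtype = subtype,
                subtypeEdgeSets = subtypeSets, gammaSite = gammaSite,
                deltaSite = deltaSite, symptomWeights = weights,
                template = template, covariateLoadings = loadings)
  list(set = set, truth = truth)
}

#' Well-separated Gaussian blobs in the plane
#'
#' Convenience generator for clustering mechanism checks.
#'
#' @param nPer Points per blob.
#' @param centers Matrix of blob centers (rows).
#' @param sd Within-blob SD.
#' @param seed RNG seed.
#' @return List with `points` (matrix) and `labels`.
#' @export
simulateBlobs <- function(nPer = 50,
                          centers = rbind(c(0, 0), c(6, 0), c(3, 6)),
                          sd = 0.6, seed = 1L) {
  set.seed(seed)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
    cbind(rnorm(nPer, centers[k, 1L], sd), rnorm(nPer, centers[k, 2L], sd))
  }))
  list(points = pts, labels = rep(seq_len(nrow(centers)), each = nPer))
}

#' Recovery report against planted ground truth
#'
#' Scores whatever components are supplied: classification accuracy of
#' predictions, precision/recall of mask-derived edges against the planted
#' discriminative set (mean case mask, top-|E*| edges), ARI of a subtype
#' assignment against the planted subtypes, and pass-through symptom r2
#' values.
#'
#' @param truth `truth` list from [simulateDataset()].
#' @param diagnosis True labels (needed with `predictions`).
#' @param predictions Optional predicted probabilities.
#' @param masks Optional list of n x n mask matrices (cases, aligned with
#'   `diagnosis == 1` subjects or all subjects; see `maskSubjects`).
#' @param maskSubjects Indices (into the dataset) of the mask list.
#' @param subtypeAssignment Optional case subtype labels (aligned with the
#'   planted `truth$subtype[!is.na(truth$subtype)]`).
#' @param symptomR2 Optional named numeric of symptom r2 values.
#' @return List of recovery metrics (only the supplied components).
#' @export
evaluateRecovery <- function(truth, diagnosis = NULL, predictions = NULL,
                             masks = NULL, maskSubjects = NULL,
                             subtypeAssignment = NULL, symptomR2 = NULL) {
  out <- list()
  if (!is.null(predictions)) {
    stopifnot(!is.null(diagnosis))
    out$accuracy <- mean((predictions > 0.5) == (diagnosis == 1))
  }
  if (!is.null(masks)) {
    meanMask <- Reduce(`+`, masks) / length(masks)
    nPl <- length(truth$plantedEdges)
    sel <- topEdges(meanMask, K = nPl)
    tp <- length(intersect(sel, truth$plantedEdges))
    out$maskPrecision <- tp / nPl
    out$maskRecall <- tp / nPl
    out$selectedEdges <- sel
  }
  if (!is.null(subtypeAssignment)) {
    ref <- truth$subtype[!is.na(truth$subtype)]
    stopifnot(length(subtypeAssignment) == length(ref))
    out$subtypeARI <- ari(subtypeAssignment, ref)
  }
  if (!is.null(symptomR2)) out$symptomR2 <- symptomR2
  out
}
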