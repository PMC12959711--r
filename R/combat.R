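## Empirical-Bayes location/scale site harmonization of edge-wise
## connectivity, with a strict fit/apply split so a model estimated on
## training subjects can be applied to held-out subjects (including
## subjects from sites never seen in training) without refitting.

#' Fit an empirical-Bayes site-harmonization model
#'
#' Fits the edge-wise linear model
#' `value = const + X beta + gamma_site + delta_site * eps` by least
#' squares (site indicators plus covariates), standardizes residuals by the
#' pooled variance, and shrinks per-site location (`gamma`) and scale
#' (`delta`) estimates with parametric empirical Bayes (normal prior on
#' additive effects, inverse-gamma prior on multiplicative effects,
#' method-of-moments hyperparameters). Diagnosis must not be included as a
#' covariate: harmonization removes site effects while preserving the
#' biological contrast, which is checked downstream, not enforced.
#'
#' @param edges Numeric matrix of edge values, edges x subjects.
#' @param sites Character/factor vector of site labels, one per subject.
#' @param covariates Optional numeric matrix/data.frame (subjects x p) of
#'   covariates whose effects are preserved (e.g. age, sex, motion).
#' @param ebTol Convergence tolerance of the empirical-Bayes fixed-point
#'   iteration.
#' @return A [CombatModel-class].
#' @export
fitCombat <- function(edges, sites, covariates = NULL, ebTol = 1e-6) {
  stopifnot(is.matrix(edges))
  N <- ncol(edges)
  sites <- as.character(sites)
  stopifnot(length(sites) == N)
  siteLevels <- sort(unique(sites))
  nPerSite <- vapply(siteLevels, function(s) sum(sites == s), integer(1))
  if (any(nPerSite < 2L)) {
    stop("fitCombat: site(s) with fewer than 2 subjects: ",
         paste(siteLevels[nPerSite < 2L], collapse = ", "), call. = FALSE)
  }
  S <- length(siteLevels)
  batch <- matrix(0, N, S, dimnames = list(NULL, siteLevels))
  batch[cbind(seq_len(N), match(sites, siteLevels))] <- 1

  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == N)
    if (is.null(colnames(covariates))) {
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    }
    if (any(apply(covariates, 2L, stats::var) == 0)) {
      stop("fitCombat: zero-variance covariate column", call. = FALSE)
    }
    covNames <- colnames(covariates)
  } else {
    covariates <- matrix(0, N, 0)
    covNames <- character(0)
  }

  design <- cbind(batch, covariates)
  xtx <- crossprod(design)
  if (rcond(xtx) < 1e-12) {
    stop("fitCombat: singular design (confounded site/covariates?)",
         call. = FALSE)
  }
  ## B: (S + p) x E coefficients
  B <- solve(xtx, crossprod(design, t(edges)))
  siteMeans <- B[seq_len(S), , drop = FALSE]
  beta <- B[-seq_len(S), , drop = FALSE]
  grandMean <- as.numeric(crossprod(nPerSite / N, siteMeans))

  fitted <- t(design %*% B)
  resid <- edges - fitted
  pooledVar <- rowSums(resid^2) / N
  if (any(pooledVar <= 0)) {
    stop("fitCombat: zero pooled variance for some edge(s)", call. = FALSE)
  }

  standMean <- grandMean + t(covariates %*% beta)  # edges x subjects
  Z <- (edges - standMean) / sqrt(pooledVar)

  E <- nrow(edges)
  gammaStar <- matrix(0, S, E, dimnames = list(siteLevels, NULL))
  deltaStar <- matrix(1, S, E, dimnames = list(siteLevels, NULL))
  gammaHat <- matrix(0, S, E)
  deltaHat <- matrix(1, S, E)
  for (s in seq_len(S)) {
    idx <- which(sites == siteLevels[s])
    Zi <- Z[, idx, drop = FALSE]
    gammaHat[s, ] <- rowMeans(Zi)
    deltaHat[s, ] <- apply(Zi, 1L, stats::var)
  }

  if (S == 1L) {
    ## no across-site prior to shrink towards
    gammaStar[1L, ] <- gammaHat[1L, ]
    deltaStar[1L, ] <- pmax(deltaHat[1L, ], 1e-8)
  } else {
    gammaBar <- rowMeans(gammaHat)
    tau2 <- apply(gammaHat, 1L, stats::var)
    ## inverse-gamma moments for the scale prior
    dMean <- rowMeans(deltaHat)
    dVar <- apply(deltaHat, 1L, stats::var)
    aPrior <- (2 * dVar + dMean^2) / dVar
    bPrior <- (dMean * dVar + dMean^3) / dVar
    for (s in seq_len(S)) {
      idx <- which(sites == siteLevels[s])
      Zi <- Z[, idx, drop = FALSE]
      ni <- length(idx)
      gOld <- gammaHat[s, ]
      dOld <- deltaHat[s, ]
      repeat {
        gNew <- (tau2[s] * ni * gammaHat[s, ] + dOld * gammaBar[s]) /
          (tau2[s] * ni + dOld)
        sum2 <- rowSums((Zi - gNew)^2)
        dNew <- (0.5 * sum2 + bPrior[s]) / (ni / 2 + aPrior[s] - 1)
        change <- max(abs(gNew - gOld) / pmax(abs(gOld), 1e-8),
                      abs(dNew - dOld) / pmax(abs(dOld), 1e-8))
        gOld <- gNew
        dOld <- dNew
        if (change < ebTol) break
      }
      gammaStar[s, ] <- gOld
      deltaStar[s, ] <- pmax(dOld, 1e-8)
    }
  }

  new("CombatModel",
      grandMean = grandMean, beta = beta, pooledVar = pooledVar,
      gammaStar = gammaStar, deltaStar = deltaStar,
      siteLevels = siteLevels, covariateNames = covNames,
      nPerSite = nPerSite)
}

#' Apply a fitted harmonization model
#'
#' Standardizes each subject with the training grand mean, covariate
#' coefficients and pooled variance, removes that subject's site effects
#' `(z - gamma*) / sqrt(delta*)`, and re-adds the grand mean and covariate
#' effects. Subjects from sites never seen during fitting are harmonized
#' with `gamma* = 0`, `delta* = 1`: no information from an unseen site can
#' exist in the model, so only the training-derived standardization is
#' applied.
#'
#' @param model A [CombatModel-class] from [fitCombat()].
#' @param edges Edge matrix (edges x subjects) to harmonize.
#' @param sites Site labels of these subjects.
#' @param covariates Covariates matching the model's `covariateNames`.
#' @return Harmonized edge matrix of the same shape.
#' @export
applyCombat <- function(model, edges, sites, covariates = NULL) {
  stopifnot(is(model, "CombatModel"), is.matrix(edges))
  N <- ncol(edges)
  sites <- as.character(sites)
  stopifnot(length(sites) == N)
  p <- length(model@covariateNames)
  if (p > 0) {
    if (is.null(covariates)) stop("applyCombat: covariates required", call. = FALSE)
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)) && ncol(covariates) == p) {
      colnames(covariates) <- model@covariateNames
    }
    miss <- setdiff(model@covariateNames, colnames(covariates))
    if (length(miss)) {
      stop("applyCombat: unknown/missing covariate(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    covariates <- covariates[, model@covariateNames, drop = FALSE]
  } else {
    covariates <- matrix(0, N, 0)
  }

  standMean <- model@grandMean + t(covariates %*% model@beta)
  Z <- (edges - standMean) / sqrt(model@pooledVar)
  out <- Z
  for (s in unique(sites)) {
    idx <- which(sites == s)
    si <- match(s, model@siteLevels)
    if (is.na(si)) {
      out[, idx] <- Z[, idx, drop = FALSE]  # unseen site: gamma*=0, delta*=1
    } else {
      out[, idx] <- (Z[, idx, drop = FALSE] - model@gammaStar[si, ]) /
        sqrt(model@deltaStar[si, ])
    }
  }
  out * sqrt(model@pooledVar) + standMean
}

#' Harmonize a ConnectomeSet in place
#'
#' Convenience wrapper: fits on (a subset of) the set and returns a new
#' `ConnectomeSet` whose `fcz` assay is harmonized, plus the fitted model.
#'
#' @param x A [ConnectomeSet-class].
#' @param covariateCols Phenotype columns to preserve as covariates
#'   (default `c("age", "sex", "motion")`, intersected with available).
#' @param fitOn Optional subject indices to fit on (default: all); the
#'   model is then applied to every subject.
#' @return List with elements `set` (harmonized ConnectomeSet) and
#'   `model` ([CombatModel-class]).
#' @export
harmonizeSet <- function(x, covariateCols = c("age", "sex", "motion"),
                         fitOn = NULL) {
  stopifnot(is(x, "ConnectomeSet"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  covariateCols <- intersect(covariateCols, colnames(cd))
  cov <- if (length(covariateCols)) as.matrix(cd[, covariateCols, drop = FALSE]) else NULL
  edges <- SummarizedExperiment::assay(x, "fcz")
  if (is.null(fitOn)) fitOn <- seq_len(ncol(edges))
  model <- fitCombat(edges[, fitOn, drop = FALSE], cd$site[fitOn],
                     if (is.null(cov)) NULL else cov[fitOn, , drop = FALSE])
  harm <- applyCombat(model, edges, cd$site, cov)
  out <- x
  SummarizedExperiment::assay(out, "fcz") <- harm
  list(set = out, model = model)
}

#' Serialize / restore a CombatModel as JSON
#'
#' Structured text serialization for audit trails.
#'
#' @param model A [CombatModel-class].
#' @param path Output file path.
#' @export
writeCombatModel <- function(model, path) {
  obj <- list(
    grandMean = model@grandMean,
    beta = model@beta,
    pooledVar = model@pooledVar,
    gammaStar = model@gammaStar,
    deltaStar = model@deltaStar,
    siteLevels = model@siteLevels,
    covariateNames = model@covariateNames,
    nPerSite = as.integer(model@nPerSite)
  )
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeCombatModel
#' @export
readCombatModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toMat <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- NULL
    m
  }
  gs <- toMat(obj$gammaStar)
  ds <- toMat(obj$deltaStar)
  rownames(gs) <- rownames(ds) <- obj$siteLevels
  beta <- toMat(obj$beta)
  if (length(obj$covariateNames) == 0L) {
    beta <- matrix(0, 0, length(obj$grandMean))
  } else {
    rownames(beta) <- obj$covariateNames
  }
  new("CombatModel",
      grandMean = as.numeric(obj$grandMean), beta = beta,
      pooledVar = as.numeric(obj$pooledVar),
      gammaStar = gs, deltaStar = ds,
      siteLevels = as.character(obj$siteLevels),
      covariateNames = as.character(obj$covariateNames),
      nPerSite = stats::setNames(as.integer(obj$nPerSite), obj$siteLevels))
}
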