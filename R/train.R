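## Training loop (Adam, early stopping on an internal validation split),
## fold construction, k-fold / leave-one-site-out protocols with
## leakage-safe harmonization, classification metrics, and fold-wise model
## comparison statistics.

## Adam update; weight decay applied to weight matrices only.
.adamStep <- function(params, grads, state, hyper, t) {
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  lr <- hyper$learning_rate
  wd <- hyper$weight_decay
  walk <- function(p, g, m, v, path = "") {
    if (is.list(p)) {
      out <- Map(function(pp, gg, mm, vv, nm) {
        walk(pp, gg, mm, vv, paste0(path, "/", nm))
      }, p, g, m, v, names(p) %||% seq_along(p))
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    isWeight <- grepl("/(W1|W2|W|w2|w)$", path)
    if (isWeight && wd > 0) g <- g + wd * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + epsA), m = m, v = v)
  }
  res <- walk(params, grads, state$m, state$v)
  list(params = res$p, state = list(m = res$m, v = res$v))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Stratified split indices: one fold id per element, balanced within strata.
.stratifiedFolds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Build cross-validation fold plans
#'
#' `kfold`: stratified by diagnosis x site; every subject appears in
#' exactly one test fold. `loso`: one fold per site. Inner folds (for
#' nested hyperparameter selection) are drawn from the outer-train subjects
#' only.
#'
#' @param diagnosis 0/1 labels.
#' @param site Site labels.
#' @param scheme `"kfold"` or `"loso"`.
#' @param k Number of outer folds (kfold only).
#' @param innerK Number of inner folds (0 to skip).
#' @param seed RNG seed.
#' @return List of folds, each with `train`, `test` and `inner` (list of
#'   `fit`/`val` index pairs).
#' @export
makeFolds <- function(diagnosis, site, scheme = c("kfold", "loso"), k = 10,
                      innerK = 0, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  N <- length(diagnosis)
  if (scheme == "kfold") {
    fold <- .stratifiedFolds(interaction(diagnosis, site, drop = TRUE), k)
    testSets <- lapply(seq_len(k), function(f) which(fold == f))
  } else {
    sites <- unique(site)
    if (length(sites) < 2L) stop("makeFolds: loso needs >= 2 sites", call. = FALSE)
    small <- sites[vapply(sites, function(s) sum(site == s) < 2L, logical(1))]
    if (length(small)) stop("makeFolds: site(s) with < 2 subjects: ",
                            paste(small, collapse = ", "), call. = FALSE)
    testSets <- lapply(sites, function(s) which(site == s))
    names(testSets) <- sites
  }
  lapply(testSets, function(test) {
    train <- setdiff(seq_len(N), test)
    inner <- list()
    if (innerK > 1L) {
      ifold <- .stratifiedFolds(
        interaction(diagnosis[train], site[train], drop = TRUE), innerK)
      inner <- lapply(seq_len(innerK), function(f) {
        list(fit = train[ifold != f], val = train[ifold == f])
      })
    }
    list(train = train, test = test, inner = inner)
  })
}

#' Train the information-bottleneck graph classifier
#'
#' Adam optimization of the composite loss with an internal stratified
#' validation split (default 10% of the training graphs) used only for
#' early stopping: training halts once validation accuracy has not
#' improved for `patience` epochs (or at the epoch cap) and the
#' best-validation checkpoint is returned. Deterministic given `seed`.
#'
#' @param graphs List of [BrainGraph-class] training graphs (both classes
#'   must be present).
#' @param hyper Hyperparameters ([defaultHyperparams()]).
#' @param seed RNG seed.
#' @param verbose Print per-epoch progress.
#' @param initParams Optional parameter list to warm-start from (defaults
#'   to a fresh [initModel()] initialization).
#' @return A trained [GraphIBModel-class].
#' @export
trainModel <- function(graphs, hyper = defaultHyperparams(), seed = 1L,
                       verbose = FALSE, initParams = NULL) {
  y <- vapply(graphs, function(g) g@label, numeric(1))
  if (length(unique(y)) < 2L) stop("trainModel: training data has a single class",
                                   call. = FALSE)
  model <- initModel(nrow(graphs[[1L]]@adjacency), hyper, seed)
  params <- if (is.null(initParams)) model@params else initParams
  ## internal validation split (stratified), carved from training data only
  nVal <- max(2L, round(hyper$val_fraction * length(graphs)))
  valIdx <- c()
  for (cls in unique(y)) {
    idx <- which(y == cls)
    take <- max(1L, round(nVal * length(idx) / length(graphs)))
    valIdx <- c(valIdx, sample(idx, take))
  }
  trIdx <- setdiff(seq_along(graphs), valIdx)
  gTrain <- graphs[trIdx]
  gVal <- graphs[valIdx]
  yVal <- y[valIdx]

  state <- list(m = .zeroLike(params), v = .zeroLike(params))
  bestParams <- params
  bestAcc <- -Inf
  sinceBest <- 0L
  t <- 0L
  hist <- list()
  for (epoch in seq_len(hyper$epochs)) {
    ord <- sample.int(length(gTrain))
    bs <- hyper$batch_size
    nb <- ceiling(length(ord) / bs)
    epochLoss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1) * bs + 1):min(bi * bs, length(ord))]
      if (length(idx) < 2L) next  # MI needs >= 2 samples
      fwd <- .forwardBatch(gTrain[idx], params, hyper, train = TRUE)
      grads <- .backwardBatch(fwd, params, hyper)
      t <- t + 1L
      upd <- .adamStep(params, grads, state, hyper, t)
      params <- upd$params
      state <- upd$state
      epochLoss <- epochLoss + fwd$loss$total * length(idx)
    }
    epochLoss <- epochLoss / length(gTrain)
    pVal <- vapply(gVal, function(g) .forwardGraph(g, params, hyper)$yhat,
                   numeric(1))
    valAcc <- mean((pVal > 0.5) == (yVal == 1))
    hist[[epoch]] <- data.frame(epoch = epoch, loss = epochLoss,
                                val_acc = valAcc)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f", epoch,
                      epochLoss, valAcc))
    }
    if (valAcc > bestAcc) {
      bestAcc <- valAcc
      bestParams <- params
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest > hyper$patience) break
    }
  }
  new("GraphIBModel", hyper = hyper, params = bestParams,
      seed = as.integer(seed), history = do.call(rbind, hist))
}

#' Predicted case probabilities
#'
#' Deterministic evaluation-mode forward pass (mask noise at its median,
#' no dropout).
#'
#' @param model A trained [GraphIBModel-class].
#' @param graphs List of [BrainGraph-class].
#' @return Numeric vector of probabilities.
#' @export
predictProb <- function(model, graphs) {
  vapply(graphs, function(g) {
    .forwardGraph(g, model@params, model@hyper)$yhat
  }, numeric(1))
}

#' Graph embeddings of the trained encoder
#'
#' Returns both the subgraph embeddings `Zsub` (the substrate for subtyping
#' and symptom regression) and the full-graph embeddings `Z`, one row per
#' subject, using deterministic masks.
#'
#' @param model A trained [GraphIBModel-class].
#' @param graphs List of [BrainGraph-class].
#' @return List with matrices `Zsub`, `Z` and vector `yhat`.
#' @export
graphEmbeddings <- function(model, graphs) {
  states <- lapply(graphs, .forwardGraph, params = model@params,
                   hyper = model@hyper)
  list(Zsub = do.call(rbind, lapply(states, `[[`, "zsub")),
       Z = do.call(rbind, lapply(states, `[[`, "z")),
       yhat = vapply(states, `[[`, numeric(1), "yhat"))
}

#' Per-subject explanation masks
#'
#' Deterministic edge masks of the subgraph generator, as n x n symmetric
#' matrices (zero off the graph's edges).
#'
#' @param model A trained [GraphIBModel-class].
#' @param graphs List of [BrainGraph-class].
#' @return List of n x n mask matrices.
#' @export
edgeMasks <- function(model, graphs) {
  lapply(graphs, function(g) {
    el <- edgeLogits(g, model@params)
    e <- sampleMask(el$omega, model@hyper$temperature)
    Mm <- matrix(0, nrow(g@adjacency), ncol(g@adjacency))
    Mm[el$edges] <- e
    Mm + t(Mm)
  })
}

#' Binary classification metrics
#'
#' Accuracy, AUC (rank statistic with midrank tie correction),
#' sensitivity, F1 and balanced accuracy at the given threshold.
#'
#' @param y True 0/1 labels.
#' @param scores Predicted scores/probabilities.
#' @param threshold Decision threshold (default 0.5).
#' @return Named list of metrics.
#' @export
classMetrics <- function(y, scores, threshold = 0.5) {
  stopifnot(length(y) == length(scores))
  pred <- as.numeric(scores > threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("classMetrics: AUC undefined with a single class", call. = FALSE)
  }
  r <- rank(scores)  # midranks
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  list(accuracy = (tp + tn) / length(y), auc = auc, sensitivity = sens,
       f1 = f1, balanced_accuracy = (sens + spec) / 2)
}

## Fit ComBat on outer-train edges only, apply everywhere; returns graphs.
.harmonizedGraphs <- function(edges, sites, cov, trainIdx, labels, n,
                              fraction) {
  model <- fitCombat(edges[, trainIdx, drop = FALSE], sites[trainIdx],
                     if (is.null(cov)) NULL else cov[trainIdx, , drop = FALSE])
  harm <- applyCombat(model, edges, sites, cov)
  buildGraphs(harm, fraction = fraction, labels = labels, nRoisOverride = n)
}

.covMatrix <- function(cset, covariateCols) {
  cd <- as.data.frame(SummarizedExperiment::colData(cset))
  covariateCols <- intersect(covariateCols, colnames(cd))
  if (!length(covariateCols)) return(NULL)
  as.matrix(cd[, covariateCols, drop = FALSE])
}

#' Nested cross-validated evaluation
#'
#' Outer k-fold cross-validation with, per outer fold: harmonization
#' fitted on the outer-train subjects only, an inner k-fold grid search
#' maximizing mean inner-fold accuracy (skipped for a size-1 grid), a
#' retrain on the full outer-train set, and evaluation on the held-out
#' fold.
#'
#' @param cset A [ConnectomeSet-class].
#' @param grid List of hyperparameter lists (each from
#'   [defaultHyperparams()]); a single-element grid reduces to plain
#'   k-fold cross-validation.
#' @param outerK,innerK Outer/inner fold counts.
#' @param fraction Edge-retention fraction for graph construction.
#' @param covariateCols Covariates preserved by harmonization.
#' @param harmonize Logical, fit/apply ComBat per fold.
#' @param seed RNG seed.
#' @return List with `folds` (per-fold metrics data.frame), `chosen`
#'   (selected hyperparameters per fold) and `summary` (mean and sd).
#' @export
nestedCV <- function(cset, grid, outerK = 10, innerK = 5, fraction = 0.2,
                     covariateCols = c("age", "sex", "motion"),
                     harmonize = TRUE, seed = 1L) {
  stopifnot(length(grid) >= 1L)
  cd <- as.data.frame(SummarizedExperiment::colData(cset))
  edges <- SummarizedExperiment::assay(cset, "fcz")
  cov <- .covMatrix(cset, covariateCols)
  folds <- makeFolds(cd$diagnosis, cd$site, "kfold", k = outerK,
                     innerK = if (length(grid) > 1L) innerK else 0,
                     seed = seed)
  perFold <- list()
  chosen <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    graphs <- if (harmonize) {
      .harmonizedGraphs(edges, cd$site, cov, fold$train, cd$diagnosis,
                        nRois(cset), fraction)
    } else {
      buildGraphs(edges, fraction, cd$diagnosis, nRois(cset))
    }
    hyper <- grid[[1L]]
    if (length(grid) > 1L) {
      gridAcc <- vapply(grid, function(h) {
        mean(vapply(fold$inner, function(inn) {
          m <- trainModel(graphs[inn$fit], h, seed = seed)
          classMetrics(cd$diagnosis[inn$val],
                       predictProb(m, graphs[inn$val]))$accuracy
        }, numeric(1)))
      }, numeric(1))
      hyper <- grid[[which.max(gridAcc)]]
    }
    model <- trainModel(graphs[fold$train], hyper, seed = seed)
    met <- classMetrics(cd$diagnosis[fold$test],
                        predictProb(model, graphs[fold$test]))
    perFold[[f]] <- data.frame(fold = f, as.data.frame(met))
    chosen[[f]] <- hyper
  }
  res <- do.call(rbind, perFold)
  list(folds = res, chosen = chosen,
       summary = data.frame(
         metric = setdiff(colnames(res), "fold"),
         mean = colMeans(res[, -1, drop = FALSE]),
         sd = apply(res[, -1, drop = FALSE], 2L, stats::sd)))
}

#' Leave-one-site-out evaluation
#'
#' One model per held-out site; harmonization is fitted on the training
#' sites only and applied to the left-out site under the unseen-site rule
#' of [applyCombat()].
#'
#' @param cset A [ConnectomeSet-class].
#' @param hyper Hyperparameters.
#' @param fraction Edge-retention fraction.
#' @param covariateCols Covariates preserved by harmonization.
#' @param harmonize Logical.
#' @param seed RNG seed.
#' @return List with `sites` (per-site metrics data.frame) and `summary`.
#' @export
losoCV <- function(cset, hyper = defaultHyperparams(), fraction = 0.2,
                   covariateCols = c("age", "sex", "motion"),
                   harmonize = TRUE, seed = 1L) {
  cd <- as.data.frame(SummarizedExperiment::colData(cset))
  edges <- SummarizedExperiment::assay(cset, "fcz")
  cov <- .covMatrix(cset, covariateCols)
  folds <- makeFolds(cd$diagnosis, cd$site, "loso", seed = seed)
  perSite <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    graphs <- if (harmonize) {
      ## held-out site is harmonized as an unseen site (gamma*=0, delta*=1)
      .harmonizedGraphs(edges, cd$site, cov, fold$train, cd$diagnosis,
                        nRois(cset), fraction)
    } else {
      buildGraphs(edges, fraction, cd$diagnosis, nRois(cset))
    }
    model <- trainModel(graphs[fold$train], hyper, seed = seed)
    met <- classMetrics(cd$diagnosis[fold$test],
                        predictProb(model, graphs[fold$test]))
    perSite[[f]] <- data.frame(site = cd$site[fold$test[1L]],
                               n = length(fold$test), as.data.frame(met))
  }
  res <- do.call(rbind, perSite)
  list(sites = res,
       summary = data.frame(
         metric = setdiff(colnames(res), c("site", "n")),
         mean = colMeans(res[, -(1:2), drop = FALSE]),
         sd = apply(res[, -(1:2), drop = FALSE], 2L, stats::sd)))
}

#' Paired fold-wise model comparison
#'
#' Paired t-test over fold-wise accuracies, Cohen's d of the differences
#' (`mean(diff)/sd(diff)`) and a percentile-bootstrap 95% CI of d.
#' Identical vectors give `d = 0`, `p = 1` by convention; zero-variance
#' non-zero differences are degenerate and reported as `NA` with a warning.
#'
#' @param accA,accB Fold-wise accuracies of the two models (equal length
#'   >= 2).
#' @param bootstrapB Bootstrap replicates for the CI.
#' @param seed RNG seed.
#' @return List with `t`, `p`, `cohens_d`, `ci95`.
#' @export
pairedFoldComparison <- function(accA, accB, bootstrapB = 10000, seed = 1L) {
  stopifnot(length(accA) == length(accB), length(accA) >= 2L)
  d <- accA - accB
  n <- length(d)
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(list(t = NaN, p = 1, cohens_d = 0, ci95 = c(0, 0)))
    }
    warning("pairedFoldComparison: zero-variance non-zero differences; ",
            "t undefined")
    return(list(t = NA_real_, p = NA_real_, cohens_d = NA_real_,
                ci95 = c(NA_real_, NA_real_)))
  }
  tstat <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  cohensD <- mean(d) / stats::sd(d)
  set.seed(seed)
  boots <- vapply(seq_len(bootstrapB), function(i) {
    db <- d[sample.int(n, replace = TRUE)]
    if (stats::sd(db) == 0) return(NA_real_)
    mean(db) / stats::sd(db)
  }, numeric(1))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(t = tstat, p = p, cohens_d = cohensD, ci95 = ci)
}

#' Learning curve over training-set size
#'
#' For each fraction, trains on that share of a stratified training split
#' and evaluates on a fixed held-out split; reports accuracy against
#' training size (trend only, no monotonicity enforced).
#'
#' @param cset A [ConnectomeSet-class].
#' @param fractions Training-set fractions in (0, 1].
#' @param hyper Hyperparameters.
#' @param fraction Edge-retention fraction.
#' @param testFraction Held-out share (default 0.3).
#' @param harmonize Logical.
#' @param covariateCols Covariates for harmonization.
#' @param seed RNG seed.
#' @return data.frame with `fraction`, `n_train`, `accuracy`, `auc`.
#' @export
learningCurve <- function(cset, fractions, hyper = defaultHyperparams(),
                          fraction = 0.2, testFraction = 0.3,
                          harmonize = TRUE,
                          covariateCols = c("age", "sex", "motion"),
                          seed = 1L) {
  if (length(fractions) == 0L) stop("learningCurve: empty fraction list",
                                    call. = FALSE)
  stopifnot(all(fractions > 0 & fractions <= 1))
  cd <- as.data.frame(SummarizedExperiment::colData(cset))
  edges <- SummarizedExperiment::assay(cset, "fcz")
  cov <- .covMatrix(cset, covariateCols)
  set.seed(seed)
  testIdx <- sort(unlist(lapply(split(seq_len(ncol(edges)), cd$diagnosis),
                                function(idx) sample(idx, round(testFraction * length(idx))))))
  trainPool <- setdiff(seq_len(ncol(edges)), testIdx)
  out <- lapply(fractions, function(fr) {
    set.seed(seed + 1L)
    take <- sort(unlist(lapply(split(trainPool, cd$diagnosis[trainPool]),
                               function(idx) sample(idx, max(2L, round(fr * length(idx)))))))
    graphs <- if (harmonize) {
      .harmonizedGraphs(edges, cd$site, cov, take, cd$diagnosis,
                        nRois(cset), fraction)
    } else {
      buildGraphs(edges, fraction, cd$diagnosis, nRois(cset))
    }
    model <- trainModel(graphs[take], hyper, seed = seed)
    met <- classMetrics(cd$diagnosis[testIdx],
                        predictProb(model, graphs[testIdx]))
    data.frame(fraction = fr, n_train = length(take),
               accuracy = met$accuracy, auc = met$auc)
  })
  do.call(rbind, out)
}

#' Graph-construction threshold ablation
#'
#' Runs the split-train-evaluate pipeline at each edge-retention threshold
#' and reports the held-out AUC, mirroring a sparsity ablation.
#'
#' @param cset A [ConnectomeSet-class].
#' @param thresholds Edge-retention fractions to compare.
#' @param hyper Hyperparameters.
#' @param testFraction Held-out share.
#' @param harmonize Logical.
#' @param covariateCols Covariates for harmonization.
#' @param seed RNG seed.
#' @return data.frame with `threshold`, `accuracy`, `auc`.
#' @export
thresholdAblation <- function(cset, thresholds = seq(0.10, 0.30, by = 0.05),
                              hyper = defaultHyperparams(),
                              testFraction = 0.3, harmonize = TRUE,
                              covariateCols = c("age", "sex", "motion"),
                              seed = 1L) {
  cd <- as.data.frame(SummarizedExperiment::colData(cset))
  edges <- SummarizedExperiment::assay(cset, "fcz")
  cov <- .covMatrix(cset, covariateCols)
  set.seed(seed)
  testIdx <- sort(unlist(lapply(split(seq_len(ncol(edges)), cd$diagnosis),
                                function(idx) sample(idx, round(testFraction * length(idx))))))
  trainIdx <- setdiff(seq_len(ncol(edges)), testIdx)
  out <- lapply(thresholds, function(th) {
    graphs <- if (harmonize) {
      .harmonizedGraphs(edges, cd$site, cov, trainIdx, cd$diagnosis,
                        nRois(cset), th)
    } else {
      buildGraphs(edges, th, cd$diagnosis, nRois(cset))
    }
    model <- trainModel(graphs[trainIdx], hyper, seed = seed)
    met <- classMetrics(cd$diagnosis[testIdx],
                        predictProb(model, graphs[testIdx]))
    data.frame(threshold = th, accuracy = met$accuracy, auc = met$auc)
  })
  do.call(rbind, out)
}

#' Serialize / restore a trained model checkpoint
#'
#' One structured-text container holding the hyperparameters, every
#' trainable weight and the training seed; restoring reproduces
#' predictions bit-wise.
#'
#' @param model A [GraphIBModel-class].
#' @param path Output file path (JSON).
#' @export
writeModelCheckpoint <- function(model, path) {
  obj <- list(hyper = model@hyper, params = model@params,
              seed = model@seed, history = model@history)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeModelCheckpoint
#' @export
readModelCheckpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  mat <- function(x) do.call(rbind, lapply(x, num))  # rowmajor nested arrays
  hyper <- lapply(obj$hyper, function(x) unlist(x))
  intFields <- c("gnn_layers", "mlp_layers", "hidden_dim", "sopool_dim",
                 "gen_hidden", "batch_size", "epochs", "patience")
  hyper[intFields] <- lapply(hyper[intFields], as.integer)
  p <- obj$params
  params <- list(
    gen = list(W1 = mat(p$gen$W1), b1 = num(p$gen$b1),
               w2 = num(p$gen$w2), b2 = num(p$gen$b2)),
    gin = lapply(p$gin, function(l) {
      list(eps = num(l$eps), W1 = mat(l$W1), b1 = num(l$b1),
           W2 = mat(l$W2), b2 = num(l$b2))
    }),
    sopool = list(W = mat(p$sopool$W)),
    head = list(w = num(p$head$w), b = num(p$head$b))
  )
  hist <- if (length(obj$history)) {
    do.call(rbind, lapply(obj$history, as.data.frame))
  } else {
    data.frame()
  }
  new("GraphIBModel", hyper = hyper, params = params,
      seed = as.integer(obj$seed), history = hist)
}

#' Read a hyperparameter configuration file
#'
#' YAML file whose fields mirror [defaultHyperparams()]; unset fields
#' take the profile defaults.
#'
#' @param path YAML file path.
#' @param profile Base profile for unset fields.
#' @return Hyperparameter list.
#' @export
readHyperparams <- function(path, profile = "desk") {
  cfg <- yaml::read_yaml(path)
  do.call(defaultHyperparams, c(list(profile = profile), cfg))
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report Result of [nestedCV()] or [losoCV()].
#' @param prefix Output path prefix (writes `<prefix>.csv` per-fold rows
#'   and `<prefix>.json` with the summary).
#' @export
writeEvalReport <- function(report, prefix) {
  rows <- report$folds %||% report$sites
  utils::write.csv(rows, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(rows = rows, summary = report$summary),
                       paste0(prefix, ".json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "rows")
  invisible(prefix)
}
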