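test_that("classification metrics match hand enumeration", {
  ## y=(1,1,0,0), scores=(0.9,0.4,0.6,0.1): one inversion of four pairs
  m <- classMetrics(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(m$auc, 0.75)   # one inversion among the four pairs
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$accuracy, 0.5)
  ## perfectly separated scores
  mp <- classMetrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(unlist(mp), c(accuracy = 1, auc = 1, sensitivity = 1,
                             f1 = 1, balanced_accuracy = 1))
  ## constant scores: AUC 0.5 by midranks
  expect_equal(classMetrics(c(0, 1, 0, 1), rep(0.3, 4))$auc, 0.5)
  expect_error(classMetrics(c(1, 1), c(0.2, 0.8)), "single class")
})

test_that("fold plans partition subjects with stratification", {
  set.seed(1)
  diagnosis <- rbinom(60, 1, 0.5)
  site <- sample(c("A", "B", "C"), 60, TRUE)
  folds <- makeFolds(diagnosis, site, "kfold", k = 5, innerK = 3, seed = 2)
  tests <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(tests, 1:60)   # every subject in exactly one test fold
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    for (inn in f$inner) {
      expect_true(all(c(inn$fit, inn$val) %in% f$train))
      expect_length(intersect(inn$fit, inn$val), 0)
    }
  }
  ## loso: one fold per site, test sets are the sites
  lf <- makeFolds(diagnosis, site, "loso")
  expect_length(lf, 3)
  for (i in seq_along(lf)) {
    expect_true(all(site[lf[[i]]$test] == site[lf[[i]]$test][1]))
  }
  expect_error(makeFolds(diagnosis, rep("A", 60), "loso"), "2 sites")
})

test_that("training is deterministic and honors patience/epoch caps", {
  graphs <- randomGraphs(24, n = 6, seed = 5)
  h <- tinyHyper(epochs = 3L)
  m1 <- trainModel(graphs, h, seed = 9)
  m2 <- trainModel(graphs, h, seed = 9)
  expect_identical(m1@params, m2@params)
  expect_identical(m1@history, m2@history)
  ## epoch cap 1: exactly one epoch
  mc <- trainModel(graphs, tinyHyper(epochs = 1L), seed = 9)
  expect_equal(nrow(mc@history), 1L)
  ## patience 0 stops at the first non-improving epoch
  mp <- trainModel(graphs, tinyHyper(epochs = 50L, patience = 0L), seed = 9)
  va <- mp@history$val_acc
  expect_lt(nrow(mp@history), 50L)
  expect_true(all(diff(va)[seq_len(nrow(mp@history) - 2)] > 0 |
                    seq_len(nrow(mp@history) - 2) == nrow(mp@history) - 1))
  expect_error(trainModel(randomGraphs(4)[c(2, 4)], h), "single class")
})

test_that("two seeds both fit an easy planted-effect training set", {
  ## strong effect: cases shifted on a block of edges
  set.seed(33)
  graphs <- lapply(1:40, function(i) {
    label <- i %% 2
    fc <- randomFC(10, seed = 100 + i, sd = 0.3)
    if (label == 1) fc[2:5, 2:5] <- fc[2:5, 2:5] + 1
    diag(fc) <- 0
    buildGraph(fc, label, fraction = 0.3)
  })
  h <- tinyHyper(epochs = 40L, patience = 40L, learning_rate = 1e-2,
                 batch_size = 20L)
  for (seed in c(1, 2)) {
    m <- trainModel(graphs, h, seed = seed)
    acc <- classMetrics(vapply(graphs, function(g) g@label, numeric(1)),
                        predictProb(m, graphs))$accuracy
    expect_gte(acc, 0.9)
  }
})

test_that("paired fold comparison matches the textbook t formula", {
  a <- c(0.74, 0.70, 0.78, 0.73)
  b <- c(0.70, 0.69, 0.71, 0.70)
  res <- pairedFoldComparison(a, b, bootstrapB = 500, seed = 1)
  d <- a - b
  tHand <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$t, tHand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(tHand), df = 3), tolerance = 1e-10)
  expect_equal(res$cohens_d, mean(d) / sd(d), tolerance = 1e-10)
  expect_true(res$ci95[1] <= res$cohens_d && res$cohens_d <= res$ci95[2])
  ## identical vectors: d = 0, p = 1 by convention
  same <- pairedFoldComparison(a, a, bootstrapB = 100)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$p, 1)
  ## constant non-zero shift: degenerate, reported NA with a warning
  expect_warning(deg <- pairedFoldComparison(a, a + 0.1, bootstrapB = 100),
                 "zero-variance")
  expect_true(is.na(deg$t))
})

test_that("learning curve and ablation harnesses run and validate input", {
  sim <- simulateDataset(simConfig(nSubjects = 60, nRois = 10, nSites = 2,
                                   nPlanted = 5, subtypeEdgeCount = 3,
                                   seed = 2))
  h <- tinyHyper(epochs = 2L)
  lc <- learningCurve(sim$set, c(0.5, 1), hyper = h, seed = 3)
  expect_equal(nrow(lc), 2)
  expect_true(all(lc$accuracy >= 0 & lc$accuracy <= 1))
  expect_gt(lc$n_train[2], lc$n_train[1])
  expect_error(learningCurve(sim$set, numeric(0), hyper = h), "empty")
  ta <- thresholdAblation(sim$set, c(0.2, 0.3), hyper = h, seed = 3)
  expect_equal(ta$threshold, c(0.2, 0.3))
  expect_true(all(is.finite(ta$auc)))
})

test_that("site relabeling leaves pooled loso predictions unchanged without harmonization", {
  sim <- simulateDataset(simConfig(nSubjects = 48, nRois = 8, nSites = 2,
                                   nPlanted = 4, subtypeEdgeCount = 2,
                                   siteAdditiveSd = 0, seed = 4))
  h <- tinyHyper(epochs = 2L)
  r1 <- losoCV(sim$set, h, harmonize = FALSE, seed = 5)
  ## relabel sites consistently; folds are the same subject groups
  cset2 <- sim$set
  cd <- SummarizedExperiment::colData(cset2)
  cd$site <- chartr("12", "21", cd$site)
  SummarizedExperiment::colData(cset2) <- cd
  r2 <- losoCV(cset2, h, harmonize = FALSE, seed = 5)
  pooled1 <- r1$sites[order(r1$sites$site), -1]
  pooled2 <- r2$sites[order(chartr("12", "21", r2$sites$site)), -1]
  expect_equal(pooled1$accuracy, pooled2$accuracy, tolerance = 1e-12)
})

test_that("nested cv with a single-config grid reduces to plain k-fold", {
  sim <- simulateDataset(simConfig(nSubjects = 48, nRois = 8, nSites = 2,
                                   nPlanted = 4, subtypeEdgeCount = 2,
                                   seed = 6))
  h <- tinyHyper(epochs = 2L)
  res <- nestedCV(sim$set, list(h), outerK = 3, seed = 7)
  expect_equal(nrow(res$folds), 3)
  expect_true(all(vapply(res$chosen, identical, logical(1), h)))
  expect_true(all(res$folds$accuracy >= 0 & res$folds$accuracy <= 1))
})

test_that("model fitting is blind to held-out rows (leakage audit)", {
  sim <- simulateDataset(simConfig(nSubjects = 40, nRois = 8, nSites = 2,
                                   nPlanted = 4, subtypeEdgeCount = 2,
                                   seed = 8))
  edges <- SummarizedExperiment::assay(sim$set, "fcz")
  cd <- as.data.frame(SummarizedExperiment::colData(sim$set))
  tr <- 1:30
  graphsAll <- buildGraphs(edges, 0.3, cd$diagnosis, nRoisOverride = 8)
  graphsTrainOnly <- buildGraphs(edges[, tr], 0.3, cd$diagnosis[tr],
                                 nRoisOverride = 8)
  h <- tinyHyper(epochs = 2L)
  m1 <- trainModel(graphsAll[tr], h, seed = 11)
  m2 <- trainModel(graphsTrainOnly, h, seed = 11)
  expect_identical(m1@params, m2@params)
  ## same for harmonization parameters
  c1 <- fitCombat(edges[, tr], cd$site[tr])
  c2 <- fitCombat(edges[, tr], cd$site[tr])
  expect_identical(c1@gammaStar, c2@gammaStar)
})

test_that("model checkpoints and hyperparameter configs round-trip", {
  graphs <- randomGraphs(12, n = 6, seed = 21)
  h <- tinyHyper(epochs = 2L)
  m <- trainModel(graphs, h, seed = 3)
  path <- tempfile(fileext = ".json")
  writeModelCheckpoint(m, path)
  back <- readModelCheckpoint(path)
  expect_equal(predictProb(back, graphs), predictProb(m, graphs),
               tolerance = 1e-12)
  expect_equal(back@hyper$hidden_dim, h$hidden_dim)
  ## YAML config overrides the profile defaults
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("hidden_dim: 12", "epochs: 7", "temperature: 0.5"), cfg)
  hy <- readHyperparams(cfg)
  expect_equal(hy$hidden_dim, 12)
  expect_equal(hy$epochs, 7)
  expect_equal(hy$temperature, 0.5)
  expect_equal(hy$alpha, defaultHyperparams()$alpha)
  ## evaluation report export
  rep <- list(folds = data.frame(fold = 1:2, accuracy = c(0.7, 0.8)),
              summary = data.frame(metric = "accuracy", mean = 0.75,
                                   sd = 0.071))
  pre <- tempfile()
  writeEvalReport(rep, pre)
  expect_true(file.exists(paste0(pre, ".csv")))
  got <- read.csv(paste0(pre, ".csv"))
  expect_equal(got$accuracy, c(0.7, 0.8))
})
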