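---
title: "Interpretable information-bottleneck graph learning for functional connectomes: models and methods"
author: "connectomeIB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{connectomeIB methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`connectomeIB` implements a two-stage analysis of case-control functional
connectivity. Stage one trains an interpretable graph classifier: a
subgraph generator learns a per-subject edge-importance mask, a graph
isomorphism network (GIN) encodes the masked graph, bilinear second-order
pooling produces a fixed-length graph embedding, and a logistic head
predicts the diagnosis, with a matrix-based Rényi mutual-information
penalty that keeps the explanation subgraph compact yet informative.
Stage two clusters the learned embeddings with density-peaks clustering
to identify patient subtypes, derives subtype-specific edge signatures
from the masks, and quantifies everything with bootstrap and permutation
statistics. A synthetic multisite benchmark with planted ground truth
exercises every step without access-restricted cohort data.

This vignette records the models, the parameters that matter, the design
choices made where the design was genuinely open, and the limitations a
user should know about.

# Data model

Connectivity is stored edge-wise: a `ConnectomeSet` extends
`SummarizedExperiment` with one assay `fcz` whose rows are the
`n(n-1)/2` undirected ROI pairs (canonical upper-triangle order,
`utPairs()`) and whose columns are subjects. Storing only the upper
triangle makes the symmetry and zero-diagonal invariants structural. The
Fisher z-transform `z = atanh(r)` is applied with correlations clamped
to `|r| <= 1 - 1e-7`, so degenerate inputs give a large finite value
rather than infinity; the diagonal is fixed at 0 by convention (its
z-value would be infinite). Node features of a `BrainGraph` are the
Fisher-z connectivity rows with zero diagonal; a configuration that
prefers raw correlations can pass `tanh`-transformed matrices, since
every operation is agnostic to the units.

Graph construction keeps the top fraction (default 20%) of edges by
absolute connectivity: exactly `round(0.2 * n(n-1)/2)` edges
(half-away-from-zero rounding; the count is 1334 at `n = 116` and 87 at
`n = 30`). Ties are broken by descending absolute value, then ascending
(row, column), so graphs are bit-reproducible.

# Multisite harmonization

`fitCombat()`/`applyCombat()` implement parametric empirical-Bayes
location/scale harmonization of the edge-by-subject matrix: an edge-wise
linear model with site indicators plus covariates (defaults
`age`, `sex`, `motion`; diagnosis is deliberately *not* a covariate —
preserving the group contrast is checked, never enforced), residual
standardization by the pooled variance, normal/inverse-gamma shrinkage of
per-site means and variances (method-of-moments hyperpriors, fixed-point
iteration to `1e-6`), and the usual back-transformation that restores the
grand mean and covariate effects.

The strict fit/apply split is the point of this implementation: the
fitted model is a frozen object that can be applied to held-out subjects
without touching their statistics. For subjects from a site never seen in
training (leave-one-site-out or cross-cohort settings), no site
parameters can exist, so the model applies only the training-derived
standardization (`gamma* = 0`, `delta* = 1`). This is a declared
convention — it guarantees that no information from the unseen site
enters the transformation. Single-site fits skip the cross-site prior
(there is nothing to shrink towards) and reduce to a near-identity.

A test cross-checks the implementation against the independent
empirical-Bayes reference in `sva::ComBat` on identical input.

# Matrix-based Rényi entropy and mutual information

For a mini-batch of embeddings, the RBF Gram matrix
`K_ij = exp(-||z_i - z_j||^2 / (2 sigma^2))` is trace-normalized and its
eigenspectrum defines the order-`alpha` entropy
`H = (1/(1-alpha)) log2 sum lambda_i^alpha` (bits, bounded by `log2 N`).
Joint entropy uses the Hadamard product of the two Gram matrices; mutual
information follows from the chain rule `MI = H1 + H2 - H12`.

Choices worth knowing:

* **Kernel width.** The width is the mean over samples of the mean
  distance to each sample's `k = 10` nearest neighbours. A single global
  width (rather than per-sample widths) keeps `K` a valid PSD kernel
  matrix.
* **Order `alpha`.** The entropy order is configurable with default
  `1.01`, a near-Shannon choice common in the matrix-entropy literature.
  Results are insensitive to `alpha` in `[1.01, 2]` on the synthetic
  benchmark.
* **Numerics.** Eigenvalues are clamped at zero, and eigenvalues below
  `N * 1e-14` of the spectral maximum are treated as exact zeros of the
  numerical rank, so rank-one matrices (identical samples) give exactly
  zero entropy even for `alpha < 1`, where tiny eigen-noise would
  otherwise be amplified by the fractional power.
* **Degenerate batches.** An all-identical embedding batch has no
  defined kernel width; its Gram matrix is taken as the all-ones matrix,
  which gives zero entropy and zero mutual information, the correct
  limit.

# The classifier

The subgraph generator is an *amortized* network: a small MLP scores the
concatenated feature pair of each existing edge and is symmetrized over
the two argument orders. Amortization is what yields masks for unseen
test subjects; per-subject free mask parameters could not generalize.
Mask values come from the binary-concrete relaxation
`e = sigmoid((logit(u) + omega) / tau)` with one shared uniform draw per
undirected edge (mirrored, so the mask stays symmetric); evaluation mode
uses the deterministic mask `sigmoid(omega / tau)`.

The encoder iterates the GIN update
`h_v <- MLP((1 + eps) h_v + sum_u A'_uv h_u)` with a two-layer ReLU MLP
per layer, where the neighbour sum is weighted by the masked adjacency
`A' = A * M` — the only way the mask influences the encoder gradient.
Bilinear second-order pooling gives the graph embedding
`h_G = flatten(W' H' H W)`, which is invariant to node reordering
(each node carries its feature descriptor). The classifier is a single
logistic unit on `h_G` of the masked pass only; the full-graph embedding
`Z` exists solely for the information-bottleneck penalty.

The composite loss is
`L = L_clf + lambda1 * MI(Z_sub, Z) + lambda2 * L_sps + lambda3 * L_ent`
with mean binary cross-entropy, the mutual-information compression term,
the mask sum (compactness) and the binary mask entropy in nats with
`0 log 0 := 0` (discreteness); per-edge sums run over the upper triangle
only and are averaged over the batch.

## Optimization and numerical choices

All gradients are derived by hand and verified against central finite
differences in the test suite. Three deliberate approximations:

* **Stop-gradient on the MI reference.** The gradient of
  `MI(Z_sub, Z)` is taken with respect to `Z_sub` only; the full-graph
  embedding `Z` and the data-derived kernel widths are treated as
  constants per batch. This keeps the penalty a pull of the subgraph
  embedding towards (the information content of) a fixed reference
  rather than letting the reference drift to meet it.
* **Graph normalization (optional).** Deep GIN stacks need activation
  control; the customary batch normalization couples graphs within a
  batch and requires running statistics. The package instead offers a
  per-channel RMS scaling across each graph's nodes — batch-independent,
  deterministic at evaluation, permutation-equivariant, and
  mean-preserving (scaling only; centering would delete exactly the
  channel means through which mean-level connectivity differences reach
  the second-order pooling).
* **Initialization.** Besides conventional He initialization, an
  `"identity"` scheme starts the GIN MLPs and the pooling projection
  near the identity with a positive first-layer bias, so units begin in
  their affine regime and the initial embedding is approximately the
  second-order statistics of the connectivity profiles. Training then
  refines an interpretable quadratic readout instead of a random one,
  which converges far faster on mean-shift connectivity signals.

Training uses Adam with decoupled weight decay on weight matrices, an
internal stratified validation split carved from the training graphs
only (early stopping monitors validation accuracy and the
best-validation checkpoint is returned), and a fully seeded RNG stream:
the same seed and configuration reproduce the model bit-wise on CPU.

Two hyperparameter profiles ship with the package.
`defaultHyperparams("full")` is the full-scale 116-ROI configuration
(5 GIN layers, 128 hidden units, batch 64, 350 epochs, dropout 0.5,
temperature 1, `lambda1 = 1e-4`, `lambda2 = 1e-5`, `lambda3 = 1e-4`,
learning rate 1e-3, weight decay 5e-4, early-stopping patience 10).
`defaultHyperparams("desk")` — the default — is the desk-scale profile
used throughout the tests: 1 GIN layer, 30 hidden units, pooling
dimension 30, identity initialization, no dropout, learning rate 3e-3,
weight decay 1e-2, 100 epochs with patience equal to the epoch cap.
The desk profile exists because a 10-epoch patience judged on a
20-subject validation split stops training essentially at random; with
the patience widened, the best-validation checkpoint still provides the
regularization.

# Evaluation protocols

`nestedCV()` runs stratified outer k-fold cross-validation (stratified
jointly by diagnosis and site to prevent degenerate folds) with, per
outer fold: harmonization fitted on the outer-training subjects only and
applied to the fold's test subjects; an inner k-fold grid search
maximizing mean inner accuracy (skipped when the grid has one entry);
retraining on the full outer-training set; and held-out evaluation.
`losoCV()` trains one model per held-out site with the unseen-site
harmonization rule. Metrics are accuracy, midrank AUC, sensitivity, F1
and balanced accuracy. `pairedFoldComparison()` provides the fold-wise
paired t-test, Cohen's d of the differences and a percentile-bootstrap
CI; identical fold vectors return `d = 0, p = 1` by convention, and a
zero-variance non-zero difference is reported as `NA` with a warning
rather than an arbitrary infinite statistic. `learningCurve()` and
`thresholdAblation()` are thin harnesses over the same machinery.

A leakage audit is part of the test suite: fitted harmonization and
model parameters are bit-identical whether or not held-out subjects are
physically present in memory during fitting.

# Subtyping

Subject distances are `1 - pearson(h_i, h_j)` between graph embeddings.
Density-peaks clustering computes Gaussian local densities
`rho_i = sum_j exp(-(d_ij / d_c)^2)`; the cutoff `d_c` defaults to the
2% quantile of pairwise distances (the usual
average-neighbourhood heuristic, configurable); `delta_i` is the
distance to the nearest denser subject (the global density maximum
receives the maximum distance; density ties are broken by index);
centers are the points with the largest prominence
`gamma = rho * delta`, either a fixed count (the reproducible default
for confirmatory analyses, e.g. 3) or the largest relative gap in the
sorted prominence sequence (`"auto"`); remaining subjects inherit the
cluster of their nearest denser neighbour in decreasing-density order.
Internal quality uses the mean silhouette width (singletons scored 0)
and the Dunn index; `K = 1` is reported as undefined.

Edge signatures take each subject's top-20 mask edges (deterministic tie
rule as in graph construction), aggregate them into per-subtype
selection frequencies `f_c(e)` (which sum to exactly 20 per subtype),
and define subtype-level top-20 sets by frequency.

Stability statistics follow the resampling design:

* **Bootstrap** (default 1000 iterations): subjects resampled with
  replacement, clustering re-run with the reference cutoff and center
  count, agreement quantified by ARI and NMI *on the unique sampled
  subjects* (duplicates collapse to one vote — a declared convention),
  subtype top-20 sets compared to the reference sets by the Jaccard
  index after greedy maximal-overlap subtype matching, and per-edge
  bootstrap selection frequencies accumulated.
* **Permutation null** (default 1000 iterations): subtype labels
  permuted, edge frequencies re-derived, empirical p-values by the
  add-one rule `(1 + #[null >= obs]) / (P + 1)`, BH-FDR adjusted over
  the family of reference edges; a size-matched random-assignment ARI
  null serves the clustering-stability comparison (reported with an
  empirical p and a Cohen's d against the null).
* **Group comparison**: pairwise two-sided Wilcoxon rank-sum tests on
  symptom scores (exact for small untied samples, normal approximation
  with tie correction otherwise), pooled-SD Cohen's d with a
  percentile-bootstrap CI, BH-FDR over the pairs.

NMI uses the arithmetic-mean normalization of the marginal entropies.
ARI delegates to the independent `mclust` implementation and is verified
against a closed-form contingency oracle in the tests.

# Brain-symptom association

`pcaReduce()` retains the smallest number of mean-centered principal
components reaching 95% cumulative explained variance. `looRidge()` then
predicts one symptom dimension per model by leave-one-out ridge
regression; within each loop the penalty is selected by inner 5-fold
cross-validation on the remaining subjects over a 21-point log-spaced
grid in `[1e-5, 1e5]` — strictly leakage-free, the conservative reading
of per-loop optimization. Performance is the cross-validated
`r2 = 1 - SS_res / SS_tot` (negative values are possible and reported
as such) and the mean absolute error. For fixed penalties the explicit
refitting loop agrees with the algebraic hat-matrix identity
`y_i - yhat_i^{loo} = (y_i - yhat_i) / (1 - h_ii)` to `1e-8`, which the
tests exploit as an independent oracle. Permutation significance reruns
the identical pipeline on permuted responses (add-one p-values, BH-FDR
across symptom dimensions).

# The synthetic benchmark

`simulateDataset()` draws, for each subject, edge values around a common
Fisher-z template (mean 0.25, SD 0.2 across edges) with residual SD 0.5;
cases receive a +0.5 shift on 15 planted discriminative edges, and each
case's subtype (three equal-sized subtypes) a +0.4 shift on its own
disjoint 10-edge signature; per-site-per-edge additive offsets
(SD 0.3) and per-site residual scale factors (uniform in `[0.7, 1.4]`)
plant the site effects; age, sex and head motion shift edges through
fixed per-edge loadings; symptom items are linear in the subject's mean
signature-edge deviation with noise at a signal-to-noise variance ratio
of 2. Defaults are 400 subjects (half cases), 30 ROIs, 3 sites. The
residual SD of 0.5 makes the planted per-edge Cohen's d approximately 1
once site and covariate nuisance is removed; the marginal d before
harmonization is attenuated to roughly 0.7-0.9 by the planted nuisance
variance, which is intended — harmonization has something real to do.
An optional time-series mode draws multivariate normal ROI series from
the implied correlation structure (eigenvalue-floored to the nearest
valid correlation matrix) so that the time-series-to-connectivity path
is exercised too.

What the generator does *not* emulate: autocorrelated BOLD noise,
heavy-tailed motion artefacts, atlas misregistration, realistic
covariance structure between edges, and site-by-diagnosis confounding.
Passing tests on this benchmark therefore demonstrate mechanism
correctness — recovery of planted effects under the stated noise model —
not clinical performance on real cohorts.

# Known limitations

* **Second-order pooling and mean-shift signals.** The bilinear pooled
  embedding is a quadratic function of the node features; statistics
  like the trace of the masked aggregation (the per-node sum of selected
  edge values), which optimally discriminate additive mean-shift
  signals, are not linearly accessible through it. On the default
  benchmark the best linear readout of the full quadratic feature space
  reaches about 0.79 held-out accuracy versus 0.90 for ridge on the raw
  edges, and the trained desk-scale model honestly reaches about 0.67
  accuracy / 0.74 AUC on a 2-fold split — comparable to the published
  range of GIN-family connectome classifiers. The edge masks, by
  contrast, separate the planted edges sharply (permutation p < 1e-3):
  the explanation pathway is more sensitive to the planted subgraph than
  the accuracy pathway. Distributed covariance-level signals, which this
  architecture targets, are not subject to this ceiling.
* **Desk scale.** Tests and the acceptance script use 30-ROI,
  400-subject problems, one CPU, and minutes of training; the full-scale
  profile is provided but not exercised at its 116-ROI size by the test
  suite.
* **Correlation-distance geometry.** Subtyping distances use
  `1 - correlation` between embeddings; embeddings whose informative
  variation is in overall magnitude rather than pattern are poorly
  separated in this geometry (the package warns against constant
  embeddings but cannot detect this milder case).
* **Permutation invariance.** Predictions are invariant to node
  relabelings in which each node keeps its feature descriptor. Because
  node features are connectivity rows, a relabeling that also reorders
  the feature coordinates changes the input itself; no architecture with
  coordinate-wise weights is invariant to that.
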