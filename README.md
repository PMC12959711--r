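# connectomeIB

Interpretable information-bottleneck graph learning and subtyping for
functional connectomes.

`connectomeIB` addresses a recurring problem in case-control resting-state
fMRI studies: classifiers over functional-connectivity (FC) matrices that
(i) generalize across acquisition sites, (ii) *explain* their decisions at
the level of individual connections, and (iii) expose the heterogeneity
hidden inside the patient group. It is written for neuroimaging
methodologists and biostatisticians who want every step — harmonization,
model, statistics — inspectable and testable on synthetic data with known
ground truth.

## The model

Each subject contributes a graph `G = (A, X)`: `A` keeps the top 20% of
edges by absolute Fisher-z correlation, and row `k` of `X` is ROI `k`'s
connectivity profile. A shared subgraph generator scores every edge and
samples a concrete-relaxed mask `M` (temperature `tau`), inducing the
explanation subgraph `A' = A ∘ M`. A GIN encoder with mask-weighted
aggregation,

    h_v ← MLP((1 + ε) h_v + Σ_u A'_uv h_u),

followed by bilinear second-order pooling `h_G = flatten(WᵀHᵀHW)` and a
logistic head predicts the diagnosis. Training minimizes

    L = L_clf + λ1·MI(Z_sub, Z) + λ2·Σ M_ij + λ3·H_b(M),

where `MI` is the matrix-based Rényi α-order mutual information between
the subgraph and full-graph embeddings (estimated from the eigenspectra of
RBF Gram matrices — no density estimation, no auxiliary network), the mask
sum enforces compactness and the binary entropy `H_b` pushes masks toward
0/1. Multisite batch effects are removed beforehand by empirical-Bayes
location/scale harmonization with strict fit/apply semantics (a model
fitted on training sites can be applied to never-seen sites without using
any of their statistics).

Downstream, patient embeddings are clustered by density peaks: local
density `ρ_i`, distance-to-denser-point `δ_i`, prominence `γ = ρ·δ`;
subtype edge signatures aggregate each subject's top-20 mask edges into
selection frequencies, with bootstrap (ARI/NMI/Jaccard) and
label-permutation statistics, and symptom scores are predicted from
PCA-reduced embeddings by leave-one-out ridge regression with permutation
significance and BH-FDR control.

## Worked example

```r
library(connectomeIB)

## a synthetic multisite cohort with planted ground truth
sim  <- simulateDataset(simConfig(nSubjects = 160, nRois = 20, nPlanted = 8,
                                  effectSize = 1.2, subtypeEdgeCount = 5,
                                  subtypeEffect = 1.2, seed = 7))
cset <- sim$set
cset
#> ConnectomeSet with 160 subjects, 20 ROIs ( 190 edges )
#>   sites: site1, site2, site3
#>   cases/controls: 80 / 80

## harmonize, build graphs, train, evaluate on held-out subjects
harm   <- harmonizeSet(cset)
graphs <- buildGraphs(harm$set)
cd     <- as.data.frame(SummarizedExperiment::colData(cset))
model  <- trainModel(graphs[1:110], defaultHyperparams(epochs = 40L), seed = 1)
model
#> GraphIBModel ( 1 GIN layers, hidden 30 , pooling dim 30 )
#>   parameters: generator 673 | encoder 1561 | pooling 900 | head 901 | total 4035
#>   trained 40 epochs; best val acc 0.875

met <- classMetrics(cd$diagnosis[111:160], predictProb(model, graphs[111:160]))
#> held-out accuracy 0.820, AUC 0.916

## explanation masks concentrate on the planted discriminative edges
masks <- edgeMasks(model, graphs[cd$diagnosis == 1])
v     <- (Reduce(`+`, masks) / length(masks))[upper.tri(diag(20))]
mean(v[sim$truth$plantedEdges])                      # 0.021
mean(v[setdiff(which(v > 0), sim$truth$plantedEdges)])  # 0.005
```

The held-out accuracy (0.82) and AUC (0.92) say the masked-subgraph
classifier separates cases from controls well beyond chance on this
cohort, and the mask means say the explanation pathway scores the planted
edges about four times higher than the rest of the graph — the edges the
model points at are the edges that actually carry the group difference.

Subtyping and its stability statistics operate on any embedding matrix:

```r
d   <- embeddingDistance(emb)          # 1 - correlation between subjects
sol <- cfdp(d, nCenters = 3)           # density-peaks solution (rho, delta, gamma)
qualitySweep(d, Ks = 2:9)              # silhouette / Dunn across K
bootstrapStability(emb, nCenters = 3, B = 1000, seed = 1)
```

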