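# odorgraph

Multi-label molecular odor prediction in R: graph neural networks against
classical descriptor-based QSOR baselines, with the full supporting
protocol — imbalance-aware losses, per-label decision-threshold
calibration, multi-label evaluation, applicability-domain assessment, and
fragment-level interpretation.

## The problem

Predicting odor from structure is a multi-label task: a molecule maps to a
vector of binary odor annotations, `f : M -> {0,1}^K` (the package is
organized around K = 6 notes: fruity, green, sweet, floral, woody,
herbal). Odor data is heavily imbalanced — per-label positive rates
typically span ~13–31% — so the pipeline is built around three ideas:

1. **Dual representation.** Molecules enter either as molecular graphs
   (25-dimensional atom features: 9-way element one-hot over
   C/N/O/S/F/Cl/Br/P/Na, atomic number, formal charge, explicit valence,
   radical electrons, explicit/implicit H, sp/sp2/sp3 one-hot, aromaticity,
   degree, and five ring flags; 6-dimensional bond features:
   single/double/triple/aromatic one-hot, conjugation, ring membership) or
   as a numeric descriptor table processed by one of three strategies —
   A: tiered imputation, IQR clipping, z-scoring; B: variance, correlation,
   mutual-information and RFE filtering down to 12–33 features per label;
   C: PCA or RBF-kernel PCA at 95% cumulative variance.

2. **Imbalance-aware training.** Three GNN architectures (GCN with
   symmetric normalization `h'_i = Σ_{j∈N(i)∪{i}} h_j W /
   √((d_i+1)(d_j+1))`, multi-head GAT, edge-conditioned NNConv) with plain,
   inverse-frequency weighted, or focal binary cross-entropy
   `L = -(1/N) Σ_i Σ_k α_k (1-p_ik)^γ log p_ik`; and six per-label tabular
   learners (RF, RBF-SVM, depth-wise GBDT, MLP, regularized and leaf-wise
   histogram boosting) behind one interface.

3. **Post-hoc calibration.** Per-label decision thresholds
   `t_k = argmax_t F1_k(validation)` over the grid 0.01…0.99, applied
   unchanged at test time. Imbalance-trained models score conservatively,
   so calibrated thresholds land below the default 0.5 and macro F1 rises
   substantially.

A synthetic-data module generates valid small molecules from a fragment
grammar, plants structure–odor rules (ester→fruity, aldehyde→green, …)
with controlled activation/background probabilities, and synthesizes a
descriptor panel with realistic pathologies (8 orders of magnitude of
column scale, tiered missingness, outliers) — so the entire pipeline is
testable end-to-end with no external data. Everything is deterministic
given a seed.

## Worked example

Generate a planted-rule study, train a GCN with focal loss, calibrate
thresholds, evaluate, and ask the model which fragments drive "fruity":

```r
library(odorgraph)

cfg    <- generation_config(600, seed = 7)
smiles <- generate_molecules(cfg)
labels <- plant_labels(smiles, cfg)
round(attr(labels, "frequencies"), 3)
#> fruity  green  sweet floral  woody herbal
#>  0.267  0.197  0.152  0.158  0.125  0.130

graphs <- smiles_to_graphs(smiles)
split  <- make_split(labels, seed = 7)          # stratified 64/16/20
model  <- train_gnn(graphs, labels,
                    gnn_config("gcn", hidden_dim = 32, n_layers = 2,
                               loss = "focal", max_epochs = 80,
                               patience = 15, seed = 7),
                    split$train, split$validation)
model
#> <trained_gnn> gcn, 2 layers x 32 hidden, loss focal; best epoch 73 (val macro F1 0.6802)

th <- optimize_thresholds(predict(model, graphs[split$validation]),
                          labels[split$validation, ])
as.data.frame(th)
#>    label threshold    f1
#> 1 fruity      0.51 0.767
#> 2  green      0.44 0.743
#> 3  sweet      0.43 0.667
#> 4 floral      0.43 0.533
#> 5  woody      0.37 0.857
#> 6 herbal      0.33 0.514

sc_test <- predict(model, graphs[split$test])
compute_metrics(apply_thresholds(sc_test, th), sc_test, labels[split$test, ])
#> macro F1 0.5997 | macro ROC-AUC 0.7937 | macro PR-AUC 0.5760 | Hamming 0.1569 | subset acc 0.3083

prof <- fragment_profile(model, graphs[split$test], labels[split$test, ],
                         apply_thresholds(sc_test, th), label_index = 1)
head(prof, 3)
#>     fragment count mean_importance total_importance
#> 4      ester    30            1.50            45.12
#> 7     ketone     2            1.91             3.82
#> 6 furan_ring     1            1.25             1.25
```

Five of six calibrated thresholds sit below 0.5 (the signature of
conservative imbalance-aware scoring), the calibrated macro F1 of 0.60 is
roughly double the label-prior floor on this data, and gradient
attribution recovers the planted ester→fruity rule: the ester group
appears in 30 of the analyzed correctly-predicted fruity molecules and
dominates the importance ranking.

The same protocol runs as one call through `run_pipeline(run_config(...))`,
which writes metrics, thresholds, gain, AD and fragment reports to a run
directory, or from the shell via `inst/cli/odorgraph.R` (`generate`,
`run-all`, `--quick`). Applicability-domain assessment
(`ad_report`) combines ECFP4 Tanimoto similarity (in-domain ≥ 0.5 to the
nearest training molecule) with minimum Euclidean distance in descriptor
or embedding space against the 95th percentile of training leave-one-out
nearest-neighbour distances.

## Package layout

- `R/mol.R`, `R/featurize.R` — SMILES parsing (OpenBabel connection
  tables) and in-package chemical perception; frozen 25/6-slot
  featurization.
- `R/smarts.R` + `inst/extdata/smarts_library.tsv` — restricted SMARTS
  matcher with atom-indexed matches; 50+ functional-group patterns.
- `R/synthetic.R` — fragment grammar, planted label rules, descriptor
  synthesis.
- `R/preprocess.R` — Strategies A/B/C.
- `R/baselines.R` — six per-label learners with CV grid search.
- `R/gnn-layers.R`, `R/gnn-train.R`, `R/losses.R` — GCN/GAT/NNConv with
  hand-derived backprop, Adam, early stopping, plateau LR decay.
- `R/threshold.R`, `R/evaluate.R` — calibration and multi-label metrics.
- `R/ad.R`, `R/interpret.R` — applicability domain, attribution and
  fragment tables.
- `R/pipeline.R` — stratified splitting and the end-to-end driver.

The methods vignette (`vignettes/odorgraph-methods.Rmd`) documents every
modelling convention, default and its rationale, and what the synthetic
benchmark does and does not demonstrate.
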