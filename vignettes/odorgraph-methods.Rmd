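---
title: "Models and methods in odorgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in odorgraph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Odor perception is a many-to-many map: one molecule can smell fruity *and*
sweet, and very different structures can share an odor note. odorgraph frames
this as multi-label classification: a function `f : M -> {0,1}^K` from
molecular structures to K binary odor annotations (the package is organized
around six classic notes -- fruity, green, sweet, floral, woody, herbal).
Two difficulties dominate real odor data and drive every design choice here:

* **class imbalance** -- positive rates per label typically sit between
  roughly 13% and 31%, so a classifier that never predicts a label looks
  deceptively good on accuracy-style metrics, and
* **representation choice** -- classical QSOR works from precomputed
  molecular descriptors, while graph neural networks learn directly from the
  bonded structure. The package implements both branches behind one
  evaluation protocol so they can be compared fairly.

# Synthetic study data

Because curated odor datasets are external and license-encumbered, the
package ships a generator that reproduces the *statistical shape* of such a
study rather than any particular dataset.

**Molecules** come from a fragment grammar: a scaffold (linear chains of 3-8
carbons, benzene, cyclopentane, cyclohexane, furan, thiophene) decorated at
open valences with 0-3 substituents drawn from 17 branch types (methyl,
two ester variants, aldehyde, alcohol, ketone, thiol, thioether, ether,
amine, carboxylic acid, nitrile, three halogens, phosphine, and a rare
sodium alkoxide). Assembly is by SMILES splicing, so every output is valid
by construction and stays inside the nine-element vocabulary
{C, N, O, S, F, Cl, Br, P, Na}; sodium appears only as a terminal alkoxide
so the 9-way one-hot is exercised without exotic valences.

**Labels** are planted by structure-odor rules: each label has a
functional-group SMARTS (ester for fruity, aldehyde for green, aliphatic
alcohol for sweet, ketone for floral, divalent sulfur for woody, benzene
ring for herbal), an activation probability for matching molecules and a
background probability for the rest. Rule probabilities and decoration
weights were fixed once so that realized label frequencies under the default
grammar span roughly 12-31% with fruity most frequent and herbal rarest,
mirroring the imbalance profile of public odor datasets. Activation >>
background means the rules are *recoverable*: a model that learns chemistry
should beat the label-prior floor, and fragment attribution should point
back at the planted groups.

**Descriptors** emulate a commercial panel at reduced width: a clean
structural block (heavy-atom / ring / heteroatom / aromatic counts, total
atomic number, and one 0/1 rule-match indicator per label -- the ground-truth
signal) padded with noise columns, ~10% of which are near-duplicates of
another column to exercise the correlation filter. Noise columns are then
degraded with log-uniform scale multipliers spanning eight orders of
magnitude, tiered missingness (columns drawn to be <5%, 5-30%, or >30%
missing) and additive outliers. Structural columns stay clean so they remain
deterministic functions of structure.

What the generator does **not** emulate: realistic odorant chemical space,
stereochemistry, 3D conformers, label hierarchies, or annotation noise that
correlates across labels. A pipeline that passes every test here has been
shown to recover planted, axis-aligned chemical signal under realistic data
pathologies -- not to predict human odor perception.

# Molecular perception and featurization

R has no RDKit; SMILES parsing is delegated to OpenBabel (through
ChemmineR/ChemmineOB), which yields a kekulized connection table. All
atom-level chemistry is perceived in-package from that table, with frozen
conventions:

* **Rings**: a bond is in a ring iff it is not a bridge; ring-size flags
  (3-6) come from explicit enumeration of simple cycles.
* **Aromaticity**: simplified Hückel rule on 5/6-membered cycles of the
  kekulized graph -- ring carbons contribute one pi electron when they carry
  a ring double bond (zero with an exocyclic double bond), pyrrole-type
  N/P and ring O/S contribute a lone pair, and the ring is aromatic at a pi
  count of six. This covers benzene, furan, thiophene, pyrrole, pyridine and
  fused benzenoids; exotic systems (azulene, tropylium) are out of scope.
* **Implicit hydrogens**: smallest allowed valence (organic-subset valence
  lists, charge-adjusted) minus the kekulized bond-order sum.
* **Hybridization**: sp for a triple bond or two double bonds, sp2 for a
  double bond or aromaticity, otherwise sp3 -- then lone-pair heteroatoms
  drawn into a conjugated system are upgraded to sp2, matching the common
  toolkit convention (ester oxygen is sp2, ethanol oxygen sp3). Anything
  else (e.g. sodium) gets an all-zero hybridization block.
* **Conjugation**: a bond is conjugated when it is aromatic, or when both
  ends are pi-capable (multiple bond or lone pair) and the pi system extends
  beyond the bond itself -- so butadiene's bonds are conjugated but
  propene's double bond and acetone's carbonyl are not.

These conventions are validated against rdkit (running as an independent
subprocess oracle in the test suite) on generated molecules for the
unambiguous properties -- atomic number, charge, degree, total hydrogen
count, aromaticity, ring membership.

The atom feature vector has exactly 25 slots in a frozen order (element
one-hot over 9 symbols; atomic number; formal charge; explicit valence;
radical electrons; explicit and implicit H counts; sp/sp2/sp3 one-hot;
aromatic flag; heavy-atom degree; any-ring flag plus 3/4/5/6-ring flags),
and the bond vector has 6 (single/double/triple/aromatic one-hot,
conjugation, ring membership). Radical parsing is not supported, so the
radical-electron slot is structurally zero; it is retained to keep the
25-slot layout stable. Feature values are *not* rescaled before the GNN --
batch normalization inside the model absorbs scale differences.

# A restricted SMARTS engine

Fragment annotation needs SMARTS matches *with atom indices*, which no
installed R binding provides (the OpenBabel binding returns counts only).
The package therefore implements a backtracking subgraph matcher for the
SMARTS subset its shipped library uses: element/aromaticity primitives,
`#n`, `X`/`D`/`H`/`R`/`r` counts, charges, negation, `&`/`,`/`;` logic,
bond symbols, branches and ring closures. Recursive SMARTS and stereo are
rejected at parse time. The matcher is cross-checked in the tests against
both OpenBabel match counts and rdkit `HasSubstructMatch` on generated
molecules. The functional-group library (50+ patterns from carboxylic acid
down to methyl) is a plain-text table with an explicit priority order:
lower numbers are more specific groups and win when a fragment overlaps
several matches.

# Descriptor processing

**Strategy A** (baseline cleaning): per-column training missing rate routes
the column to median imputation (<5%), 5-nearest-neighbour imputation
(5-30%), or removal (>30%). KNN distances are Euclidean over the columns
observed in both rows, computed on a median-pre-imputed, internally
standardized copy -- pre-imputation breaks the circularity of computing
distances on incomplete data, and the internal standardization stops
large-scale columns from dominating the metric. Surviving columns are
clipped to `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` and z-scored. Quartiles use
linear interpolation (R type 7); the convention matters because clip bounds
depend on it, so it is frozen and documented. **Binary two-valued columns
are exempt from clipping**: a minority indicator has Q1 = Q3, so the IQR
rule would flatten it to a constant and destroy exactly the kind of sparse
structural signal descriptor panels encode. All parameters come from
training rows only and are reused unchanged for validation/test rows; the
transform is idempotent to 1e-9.

**Strategy B** (per-label selection): variance filter (tau = 0.01), then a
global left-to-right correlation filter (|rho| > 0.95 drops the later
column -- deterministic, and applied globally rather than per label since
redundancy is a property of the feature table), then per label a mutual
information ranking keeping the top 64 candidates, then recursive feature
elimination. MI uses the k-nearest-neighbour estimator for a continuous
feature against a discrete target (k = 3), with a deterministic
sub-resolution jitter to break ties. RFE eliminates by absolute coefficient
of an L2-regularized logistic model, and candidate subset sizes spanning
12-33 are scored by 5-fold stratified cross-validated F1. The ridge penalty
is `lambda = 0.1`: with separable planted indicators a vanishing penalty
lets the ridge solution diverge and the returned coefficients are
meaningless, so the penalty must stay meaningfully positive.

**Strategy C** (reduction): PCA keeps the smallest component count whose
cumulative explained variance reaches 0.95. Kernel PCA uses an RBF kernel
with the median-pairwise-distance bandwidth heuristic on training rows, and
applies the same cumulative rule to the eigenvalues of the doubly centered
kernel matrix -- the eigendecomposition is done explicitly because the rule
needs *all* eigenvalues, not just the leading ones. Both are fitted on
training rows only.

# Baseline learners

Six model kinds, one independent binary classifier per label (binary
relevance -- the natural reading of per-label stratified protocols).
Backends: ranger (random forest), e1071 (RBF SVM with Platt-scaled
probabilities), nnet (single-hidden-layer MLP), and xgboost for all three
boosting kinds with genuinely different configurations: `gbdt` is classic
depth-wise boosting (depth 3, learning rate 0.05, row/column subsampling),
`xgboost` the default regularized setup, and `lightgbm` a leaf-wise
histogram configuration (`grow_policy = "lossguide"`, leaf-count limited) --
the latter is this package's leaf-wise GBDT, not the LightGBM library.
Hyperparameter grids are deliberately small (two to four points) and are
searched by stratified cross-validated F1 at threshold 0.5. All kinds are
deterministic given the seed with one thread.

# Graph neural networks

Three architectures over the shared featurization, each implemented with an
explicit hand-derived backward pass (verified against numerical gradients
to ~1e-9 in the tests):

* **GCN**: symmetric-normalized convolution with self-loops,
  `h'_i = sum_{j in N(i) u {i}} h_j W / sqrt((d_i+1)(d_j+1))`.
* **GAT**: additive attention per head over `N(i) u {i}`, softmax-normalized
  per destination; heads concatenated in hidden layers and averaged in the
  final graph layer. Attention weights are retained for interpretation.
* **NNConv**: per-edge transforms generated from the 6-dimensional bond
  vector by a small linear-ReLU-linear edge network; messages
  `Theta(e_ij) h_j` are mean-aggregated (sum aggregation scales with degree
  and destabilizes training on mixed-size molecules) and combined with a
  root transform. Since bond vectors take few distinct values, edge
  transforms are computed once per unique bond type per batch.

Each graph layer is followed by batch normalization, ReLU and dropout;
global mean pooling produces the graph embedding (also the vector the
applicability-domain analysis uses), followed by a two-layer head with
sigmoid outputs. Losses: plain BCE, inverse-frequency weighted BCE
(`w_k = (N - n_k)/n_k` on the positive term), and focal loss
`-(1/N) sum_i sum_k alpha_k (1 - p_ik)^gamma log p_ik` with `p_ik` the
confidence in the true class; `gamma = 0, alpha = 1` recovers BCE exactly.
Scores at exactly 0 or 1 are clamped at 1e-7 before taking logs.

Training is mini-batch Adam with early stopping and plateau learning-rate
decay. **Model selection monitors calibrated validation macro F1** -- the
macro F1 at per-label F1-optimal thresholds on the validation scores --
rather than macro F1 at a fixed 0.5. The fixed-0.5 metric is recorded in
the history, but it is a pathological monitor for imbalance-aware losses:
focal training produces deliberately conservative scores, the 0.5-threshold
F1 collapses to zero for every competent checkpoint, and the selector then
retains near-initial weights. Monitoring the calibrated quantity uses only
the validation rows that post-hoc calibration uses anyway, so the leakage
discipline is unchanged. Default sizes (3 layers, hidden 64, 4 heads,
dropout 0.2, batch 32, learning rate 1e-3, patience 20, decay 0.5 after 10
flat epochs) are desk-scale choices; the test suite and the acceptance
script train 2-layer, hidden-32 models on 600 molecules, which one CPU
handles in well under a minute per model.

Everything is deterministic given the config seed: initialization, batch
shuffling and dropout all flow from R's generator, and the linear algebra
is single-threaded base R.

# Threshold calibration

For each label independently, the decision threshold scans the grid 0.01,
0.02, ..., 0.99 and keeps the value maximizing that label's validation F1;
predictions use `score >= t`. The 0.01 resolution and the `>=` boundary are
frozen for bit-reproducibility; ties break toward the smaller threshold,
which favors recall -- the right bias for models already known to be
conservative. Labels with no validation positives get t = 0.5 with a
warning. F1 with no predicted and no true positives is defined as 0. Gain
accounting reports absolute (after - before) and relative
(100 x absolute / before, one decimal, NA at before = 0) improvements.

# Evaluation

Per label: precision, recall, F1 (= 0 when P + R = 0), trapezoidal ROC-AUC
over unique score thresholds (equal to the normalized Mann-Whitney U
statistic with ties counted half), and step-interpolated PR-AUC
(average-precision style; trapezoidal PR areas are optimistically biased).
Aggregates: unweighted macro means, Hamming loss (fraction of wrong cells)
and subset accuracy (fraction of rows with all labels correct). A label
with a single class in the truth has undefined ROC-AUC; it is reported as
NA with a warning and excluded from the macro mean rather than imputed.

# Applicability domain

Two complementary judgments per test molecule, combined conservatively:

* **Tanimoto**: ECFP4 circular fingerprints (radius 2; the OpenBabel
  4096-bit implementation folded to 2048 bits by OR-ing halves), in-domain
  when the maximum similarity to any training molecule reaches 0.5.
* **Distance**: minimum Euclidean distance to the training set -- processed
  descriptors for tabular models, pooled GNN embeddings for graph models --
  with the threshold read as the 95th percentile (type 7) of the training
  set's *leave-one-out nearest-neighbour* distances. "95th percentile of
  training set distances" admits several readings; the LOO-NN reading is
  the only one on the same scale as a test molecule's nearest-neighbour
  distance, and it is documented here as the package's definition.

The combined flag requires both methods in-domain (so its percentage can
never exceed either method's), and the agreement rate is the fraction of
samples on which the two methods concur.

# Interpretability

Node importance comes from two routes: **gradient attribution** -- the sum
of absolute input-gradients of the target label's pre-sigmoid logit over an
atom's 25 feature slots (absolute gradient is the least-assumption variant;
gradient-times-input would entangle importance with the feature encoding's
arbitrary scales) -- and, for GAT, **attention importance**
`I_i = (1/(L H)) sum_l sum_h sum_{j in N(i)} alpha_ij`, the attention mass a
node's neighbours receive in its aggregation, averaged over layers and
heads. The neighbour sum excludes the self-loop (an isolated atom has
importance 0 even though its self-attention is 1 by softmax normalization).

Fragments are extracted per molecule: atoms at or above the 75th percentile
(type 7, ties included) of that molecule's importance scores are grouped
into connected components by BFS over the bonds, and each component is
labelled with the highest-priority SMARTS library group overlapping it, or
"small fragment". The percentile is per-molecule, not global -- a molecule
with uniformly low scores still reports its own most salient region. Per
label, up to 30 correctly predicted positive test molecules are analyzed
and fragments aggregated by occurrence count, mean importance and total
importance (the ranking key).

# Orchestration and leakage discipline

`make_split` implements greedy iterative stratification (rarest label
first, each positive assigned to the split with the largest remaining
demand, subject to exact split capacities at the 64/16/20 fractions), with
a random fallback when a label has fewer than three positives. Both split
modes are available; stratified is the default for all model families --
stratification is strictly safer, and nothing in the protocol depends on
GNNs using random splits. `run_pipeline` asserts the three index sets are
disjoint, computes preprocessing statistics and feature selections on
training rows only, calibrates on validation rows only, and touches test
rows exactly once, at final scoring. Reruns with the same configuration
reproduce every metric bit-for-bit.

# Known limitations

* Perception is heuristic beyond the grammar's chemistry: kekulized-input
  aromaticity handles common heteroaromatics only, and hybridization /
  conjugation are convention-matched rather than electronic-structure
  derived.
* The SMARTS engine covers the shipped library's subset, not the full
  language.
* Pure-R training limits practical scale to a few thousand small molecules;
  the implementation is exact, just not fast.
* Synthetic labels are axis-aligned single-group rules plus independent
  noise; real structure-odor relationships involve group interactions and
  perceptual label correlation that the generator deliberately omits.
* The attention-importance accessor reports softmax-normalized attention,
  which is a descriptive summary of message routing, not a causal
  explanation.
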