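---
title: "Graph-convolutional multi-omics classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional multi-omics classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

omicsgraphnet classifies cancer versus non-cancer samples from paired
gene-expression and DNA-methylation blocks. Instead of treating samples
as independent observations, each omics block induces a
*sample-similarity graph*, and a graph convolutional network (GCN)
propagates each sample's feature vector through its neighborhood before
classification. Two per-omics classifiers are then fused by a small
terminal ("Mutation FC") layer, to which rule-based therapy annotations
from DNA-sequencing variants are attached. This vignette documents the
model, its assumptions, the tunable parameters, the numerical choices,
and what the synthetic experiments do and do not establish.

## The model

### Sample-similarity graphs

For an omics block $X \in \mathbb{R}^{n \times p}$ (samples in rows),
the adjacency is thresholded cosine similarity,

$$A_{ij} = \mathrm{sim}(x_i, x_j)\,\tilde\delta_{ij}, \qquad
  \mathrm{sim}(x_i, x_j) = \frac{x_i \cdot x_j}{\lVert x_i\rVert\,\lVert x_j\rVert},$$

with $\tilde\delta_{ij} = 1$ for $i \neq j$ and 0 on the diagonal, and
similarities below a threshold $\tau$ set to zero (ties at exactly
$\tau$ are kept). Self-loops enter only through the symmetric
normalization

$$\hat A = \tilde D^{-1/2}(A + I_n)\tilde D^{-1/2},
  \qquad \tilde D_{ii} = \sum_j (A + I_n)_{ij},$$

which is always defined because every degree is at least 1. When $A$ is
non-negative, the spectrum of $\hat A$ lies in $[-1, 1]$, which keeps
repeated propagation stable.

**Choosing $\tau$.** The threshold controls graph density. Rather than
fixing an arbitrary value, `select_threshold()` picks the largest
$\tau$ whose mean retained degree meets a target (default 10 neighbors
per sample). This reduces to an order statistic — the $m$-th largest
off-diagonal similarity with $m = \lceil \text{target} \cdot n \rceil$
— and is verified in the tests against a brute-force scan. A degree
target of about 10 keeps the graph sparse enough that neighborhoods
stay class-coherent at cohort sizes of a few hundred, yet dense enough
that no sample is isolated; both the explicit `tau` and the degree
target are exposed.

**Negative similarities** surviving a negative $\tau$ are kept as-is;
clamping would be an extra undocumented transformation, and the
normalization formula does not require non-negativity (only the
spectral guarantee does).

### Per-omics GCN modules

Each layer propagates activations one hop and applies LeakyReLU with
negative slope 0.25:

$$H^{(d+1)} = \sigma\!\left(\hat A H^{(d)} W^{(d)}\right),
  \qquad H^{(0)} = X.$$

A module stacks two graph-convolution layers ($p \to 400 \to 400$) —
the canonical depth for this family of models, configurable from 1 to
3 — followed by fully connected layers $400 \to 200 \to 2$. Neighbor
aggregation is the weighted sum implied by $\hat A$. Dropout (rate
0.5) is applied to the inputs of the fully connected layers during
training only; graph-convolution layers are left undropped by default
since their weights are shared across all positions of a sample's
neighborhood.

### Fusion and therapy annotation

The two modules emit per-sample 2-class score rows
$\hat y_{1k}, \hat y_{2k}$. The terminal layer concatenates them and
applies one affine map,
$F(\hat y_{1k}, \hat y_{2k}) = W^\top [\hat y_{1k}; \hat y_{2k}] + b$,
producing the final logits. We deliberately fuse the 2-dimensional
score rows (4 inputs per sample) rather than the 200-dimensional
penultimate activations: both readings of the architecture are
defensible, the low-dimensional head follows the fusion loss's symbols
literally, and it keeps the head's capacity too small to override a
disagreeing module on its own.

Genomic variants (SNVs, indels, fusions, rearrangements) do not enter
the gradient path. They drive a rule-based lookup
(`match_therapy()`): each (gene, alteration-pattern, agent) rule
annotates matching samples with candidate targeted agents. The package
ships a minimal, deliberately editable starting table
(`default_therapy_rules()`); any institutional table can be supplied
as a 3-column TSV. Annotation never changes class probabilities.

### Losses and the two-stage schedule

Per-module and fusion losses are **summed** (not averaged)
cross-entropies over the training samples,

$$L_{GCN_l} = \sum_{k=1}^n CE(y_k, \hat y_{lk}), \qquad
  L_F = \sum_{k=1}^n CE(y_k, F(\hat y_{1k}, \hat y_{2k})),$$

combined as $L = \sum_l \alpha_l L_{GCN_l} + \lambda L_F$ with all
$\alpha_l = 1$ (the stable setting) and $\lambda = 1$ by default
($\lambda$ is exposed; $\lambda = 0$ provably decouples the modules,
which the tests exploit). Because sums scale with $n$, nominal
learning rates interact with cohort size; Adam's per-parameter
normalization absorbs most of this, but the scaling is worth knowing
when transferring learning rates between cohorts.

Training runs in two stages with three separate learning rates, all
drawn from the shared grid
$\{10^{-7}, 5\times10^{-7}, \dots, 10^{-3}, 5\times10^{-3}\}$:

1. **Pretraining** (default 500 epochs, `lr_pretrain`): each omics
   module trains alone on its own affinity-weighted loss; the fusion
   head is untouched.
2. **Fine-tuning** (default 2500 epochs): all modules (`lr_train`) and
   the head (`lr_terminal`) minimize $L$ jointly.

`grid_search_learning_rates()` scores triples by mean validation macro
F1 under stratified k-fold cross-validation, breaking ties toward the
smaller `lr_train`, then `lr_pretrain`, then `lr_terminal`. The full
grid has 1000 triples; the desk-scale default searches the 10-point
diagonal.

### Weight smoothing before pretraining

Two concrete smoothing steps realize the idea that protruding
components of sample weight vectors should be restrained and that a
sample's link to a label should be discounted when its neighborhood
disagrees:

* **Feature clipping**: values farther than `clip_sd` (default 3)
  standard deviations from the feature mean (both computed on the
  training partition) are clipped to that bound.
* **1-hop label affinity**: each training sample's cross-entropy term
  is weighted by the fraction of its labeled 1-hop neighbors sharing
  its class; samples with no labeled neighbors get weight 0.5. A
  class-0 sample sitting amid class-1 neighbors therefore contributes
  less during pretraining, smoothing the decision field. Affinity
  weighting applies to pretraining only and can be disabled
  (`use_affinity = FALSE`), as can clipping (`clip_sd = Inf`).

### Transductive inference and standardization

Training and test samples share one cohort. `gcn_fit()` builds the
similarity graphs over *all* samples and masks non-training labels
(their loss weight is zero), so test samples are scored inside the
same graph they will be predicted in — transductive inference,
matching a fixed-split, single-cohort design. Nothing from test
*labels* leaks into training; the tests confirm chance-level held-out
accuracy on null cohorts.

Before graph construction, `gcn_fit()` standardizes every feature
(log1p for expression, then z-scoring by training-partition mean and
SD, applied to all rows). Raw linear-scale expression would otherwise
dominate the cosine similarity through overall intensity rather than
profile shape, and would put the two omics blocks on incomparable
scales. Users with already-normalized matrices can pass
`standardize = FALSE`.

## Two-stage biomarker identification

1. **Primary filter.** Welch's unequal-variance t-test per feature
   (cancer vs non-cancer) with strict thresholds: $p < 0.05$ and
   $|\log_2 FC| > 0.5$ for expression (group means on the linear
   scale, pseudocount 1). Methylation beta values cannot support a
   fold-change rule — a shift from 0.4 to 0.6 is biologically large
   but only 0.58 on the log2 scale while the same rule would pass
   tiny absolute changes near 0 — so the methylation filter uses the
   absolute difference in mean beta value, default threshold 0.2
   (configurable). Boundary values are dropped on both rules (strict
   inequalities). No multiple-testing correction is applied at this
   stage; the filter is a pre-screen, not an inference.
2. **Influence ranking.** For each surviving feature $G_n$, the
   influence is $\Delta F1(G_n) = F1_{\text{with}} -
   F1_{\text{without}}$, macro F1 on the validation partition. The
   default "mask" mode replaces the feature column by its
   training-set mean and reuses the trained model *and* its graph;
   rebuilding the $n \times n$ similarity graph per feature would
   cost $O(n^2 p)$ per feature with no stated benefit, and a
   mean-imputed column is the natural "feature absent" limit for a
   standardized input. A "retrain" mode (same seed, feature removed)
   exists behind a flag for small problems. Ties in $\Delta F1$ —
   common, because masking one of many redundant informative features
   often flips no prediction — are broken by larger $|t|$, then
   feature ID, so the ranking degrades gracefully toward the
   univariate ordering. The top 200 expression and 300 methylation
   features are kept by default.

## Evaluation

Seven metrics are computed from the positive-class = cancer
convention: sensitivity, specificity, accuracy, precision, AUC-ROC
(Mann–Whitney midrank form), macro F1 (unweighted mean of the
per-class F1s), and weighted F1. The count-weighted form
$(n_+ F1_+ + n_- F1_-)/(n_+ + n_-)$ is the default weighted F1; the
variant that divides by 2 instead is available as
`variant = "as_printed"` with a warning, since it exceeds 1 whenever
$n > 2$ and cannot be what any percentage-scale report means.
Degenerate ratios (0/0) return 0 with a warning rather than erroring,
so cross-validation folds with an empty predicted class still
aggregate.

Baselines — a 1-D CNN (max pooling kernel 2, stride 1, zero padding),
a logistic-regression head with per-batch feature normalization, and a
naive-Bayes-structured network whose standard-normal weight prior is
realized as the equivalent L2 log-prior penalty — share the GCN's
activation, optimizer, loss, hidden width (400) and FC dimension
(200), and are trained on the column-bound omics blocks.
`compare_models()` runs every model on identical stratified folds and
reports mean ± SD of all seven metrics across folds (error bars are
over folds, not repeated runs).

## Data splitting

`split_dataset()` stratifies by class at 55/15/30
(train/validation/test) with largest-remainder rounding applied so
that *both* the overall part sizes and the per-class quotas are met
exactly; `kfold_splits()` deals shuffled samples per class onto the
currently lightest folds, keeping fold sizes and per-fold class
balance within one sample. Both are deterministic per seed. Classes
with fewer than 3 samples cannot be stratified three ways and are
rejected.

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a paired
expression/methylation NSCLC cohort with known ground truth:

* **Expression**: log-normal per feature (log-scale SD 0.5,
  log-means drawn around 2), features grouped in blocks of 10 sharing
  an equicorrelation factor (default 0.3). Informative features shift
  the cancer-class mean on the **log scale** by
  `effect_size` × SD(log), alternating up-/down-regulation. Values
  stay positive and are *not* centered, so linear-scale fold changes
  remain well-defined; the model's own standardization happens inside
  `gcn_fit()`.
* **Methylation**: Beta-distributed with concentration 10,
  moment-matched means; informative CpGs shift the cancer mean by
  `effect_size` × SD(beta), alternating hyper-/hypomethylation.
  Informative base means are drawn from [0.3, 0.7] so the shifted
  mean stays inside (0.05, 0.95) without clamping away the group
  difference.
* **Variants**: Bernoulli per (sample, driver gene) at class-specific
  rates (defaults 0.30 cancer / 0.02 control), with
  fusion-type alterations for the known fusion drivers.

The defaults — 150 + 150 samples, 200 expression + 300 methylation
features with 20 + 30 informative at effect size 1.5 — mirror the
post-selection dimensions of the reference protocol and are the
conditions under which the acceptance experiments run. The
`generate_separable_toy()` variant (10 + 10 features, effect 3) is
the near-separable cohort used by convergence tests.

What the generator does **not** model: count noise and library-size
effects, probe chemistry and batch effects, survival outcomes, or any
real linkage between a sample's variants and its expression profile.
Passing tests on these cohorts therefore establish that the
implementation is correct and that the pipeline recovers planted
signal at realistic dimensions — not that the model attains any
particular performance on real tumor cohorts.

## Numerical choices and degenerate inputs

* Cross-entropy probabilities are clamped to $[10^{-12}, 1-10^{-12}]$,
  so confidently wrong predictions yield large finite losses.
* Xavier (Glorot-uniform) initialization throughout; every stochastic
  step — initialization, dropout, splits, generation — is governed by
  explicit integer seeds, and each module draws its dropout from its
  own per-epoch stream, which is what makes $\lambda = 0$ fine-tuning
  bit-identical to independent training.
* Training runs full-batch (no mini-batching, schedulers, or early
  stopping): cohorts of a few hundred samples fit comfortably in
  memory and fixed epoch counts keep runs reproducible.
* A non-finite loss aborts with the offending epoch in the message.
* Zero-norm samples are rejected before cosine similarity; zero-
  variance features are excluded from testing with a warning;
  isolated graph nodes fall back to uniform label affinity.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` train the full pipeline at
the default 300-sample, 500-feature conditions with 500 pretraining
plus 500 fine-tuning epochs — enough for the loss to plateau on these
cohorts while keeping a multi-seed experiment comfortably runnable on
a laptop CPU; the package default of 2500 fine-tuning epochs remains
the reference setting for real cohorts. Unit tests use smaller toys
(20–60 samples, 16–400 hidden units) chosen to exercise every code
path rather than to reach peak accuracy.

## Known limitations

* Exactly two omics blocks are fused; the head generalizes trivially
  but `predict.gcn_fit()` currently asserts two modules.
* Binary labels only (cancer vs non-cancer); subtype classification
  is out of scope.
* Transductive scoring means adding new samples requires re-running
  the forward pass on the extended graph (cheap), and strictly
  out-of-graph inductive prediction is not offered.
* The therapy rule table is illustrative, not clinical guidance.
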