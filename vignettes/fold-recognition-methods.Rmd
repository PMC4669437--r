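---
title: "Deep-network protein fold recognition: models, protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-network protein fold recognition: models, protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Template-based protein structure prediction starts with *fold
recognition*: given a query protein of unknown structure, rank a library
of template domains of known structure by how likely each is to share the
query's structural fold. The task is posed here as pairwise binary
classification. Every ordered (query, template) pair of domains is
described by a fixed-width vector of pairwise similarity features
(sequence-sequence, sequence-profile and profile-profile alignment
scores, predicted structural features and so on — 84 features in the
classic setting), and a classifier predicts whether the two domains share
a fold. Candidate templates are then ranked per query by the predicted
score.

Difficulty is graded by the SCOP hierarchy. Pairs in the same *family*
still share detectable sequence similarity; pairs that share only a
*superfamily* are harder; pairs that share only a *fold* have little or
no sequence similarity and are the hardest. Each pair is labelled with
its **most specific** shared level (FAMILY, SUPERFAMILY, FOLD, or NONE),
so the three positive sets are disjoint, and the binary positive class is
their union.

```{r}
library(dnfold)
scop_relationship("a.1.1.1", c("a.1.1.1", "a.1.1.2", "a.1.2.1", "b.1.1.1"))
```

## Models

### The RBM-pretrained classifier

`dnfold_fit()` trains a feed-forward network with sigmoid hidden units and
a single sigmoid output. Weights between adjacent layers are initialized
by stacking restricted Boltzmann machines: the first RBM is trained on the
(min-max scaled) features by one-step contrastive divergence (CD-1), its
hidden activation probabilities become the visible data of the next RBM,
and so on up to the last hidden layer. A randomly initialized output unit
is then added and the whole stack is fine-tuned by mini-batch
backpropagation minimizing binary cross-entropy. The default architecture
is `F-100-100-35-1`.

The generative pretraining matters even at small scale: with near-zero
initial weights a deep sigmoid network sits at a symmetric saddle where
backpropagated gradients nearly vanish; the CD-1 epochs grow the weights
into a representation that already separates the classes coarsely, after
which fine-tuning converges quickly.

Tunable parameters (see `dnfold_control()`), with defaults:

* `batch_size = 1000` examples. This default is sized for benchmark-scale
  inputs of order $10^6$ pairs; for desk-scale datasets of a few hundred
  to a few thousand pairs we use `batch_size = 32` throughout this
  package's experiments, which keeps the number of gradient updates per
  epoch comparable instead of collapsing an epoch into a single full-batch
  step.
* `pretrain_epochs = 25`, `finetune_epochs = 25`. An
  `architecture_spec()` can carry its own fine-tuning epoch count, which
  takes precedence (the candidate pool uses 30 or 60).
* RBM hyperparameters follow standard CD-1 practice: learning rate 0.1,
  momentum 0.5 for the first 5 epochs then 0.9, weight decay `2e-4`,
  weights initialized N(0, 0.01²), zero biases. Backpropagation uses the
  same learning rate and momentum schedule, no weight decay.
* `positive_weight` can up-weight the positive class in the
  cross-entropy. Benchmark-scale data are extremely unbalanced (roughly
  one positive per seven hundred pairs); the default is no reweighting,
  matching the ranking use of the scores, and the flag exists for
  experimentation.
* `seed` drives every random draw (RBM initialization and sampling, the
  output-layer initialization, the per-epoch batch shuffles). Training is
  reproducible bit for bit given data, configuration and seed; package
  functions restore the caller's RNG state.

Labels are `{0, 1}` with a sigmoid output rather than the `{-1, +1}`
convention sometimes used for this problem, because binary cross-entropy
requires targets in `[0, 1]`; the two encodings are equivalent for
ranking.

Features are min-max scaled per feature to `[0, 1]` using training-set
statistics stored in the model and re-applied at prediction time. The
first RBM treats its visible units as Bernoulli activation probabilities,
so its inputs must live in `[0, 1]`; scaling is the simplest map with
that property. Constant features map to 0.

### The TM-score regressor

Fold membership is a binarization of a continuous structural-similarity
landscape, and near the decision boundary (TM-scores roughly 0.30-0.50)
same-fold and different-fold pairs overlap heavily. `dnfoldr_fit()`
therefore learns the TM-score itself: a network with two rectified-linear
hidden layers and a linear output, all weights initialized uniformly in
`[-0.5, 0.5]`, trained by plain SGD (learning rate 0.01, up to 50 epochs)
on the mean squared error — the Gaussian log-likelihood up to an additive
constant and a variance factor that does not move the optimum. Predicted
scores are clamped to `[0, 1]` for reporting and ranking; the loss is
computed on the unclamped output. The regression label for a pair takes
the TM-score normalized by the shorter chain when the pair shares a fold
and the longer-chain normalization otherwise (`choose_tm_label()`),
which is how the reference similarity labels are constructed. Pairs with
no TM-score are dropped with a logged count.

The default regressor architecture has exactly two hidden layers
(`F-100-100-1`); any depth is accepted via `arch`.

### Ensembling and the meta-combiner

`default_architecture_pool()` reproduces the 14 candidate classifier
architectures (one to three hidden layers, 30 or 60 fine-tuning epochs).
`cv_predict_pool()` gives each member out-of-fold predictions on a shared
partition; `sequential_ensembles()` sorts members by AUC ascending (ties
by pool index, for determinism) and averages the `k` lowest-AUC members
for `k = 1 … 14`, recomputing each ensemble's AUC. The final
fold-recognition score averages **all** 14 members. `meta_sum()`
implements the score-sum meta-combination with a second method's scores
(e.g. a random-forest fold recognizer); both inputs must be on a common
`[0, 1]` scale — the sum is only used for ranking. Member AUCs are
computed on out-of-fold predictions pooled across folds with all positive
levels combined.

## The evaluation protocol

`make_cv_partition()` implements query-grouped 10-fold cross-validation:
all pairs sharing a query go into that query's fold, and the
template-removal rule discards any test pair whose template serves as a
query in that round's training set. With a complete all-against-all pair
set this leaves, for each round, exactly the pairs whose template is
grouped in the same fold (or is never a query); those survivors are
scored once each by a model that never saw them (`cv_predict()`).

`topk_success_rate()` computes the per-level success rates: for level
$L$, pairs *more* specific than $L$ are excluded from each query's ranked
candidate list (family pairs do not compete when superfamily recognition
is scored), a query counts only if it retains at least one pair at
exactly level $L$, and it succeeds when such a pair ranks in the top
$k$. With no evaluable query the rate is explicitly undefined (`NA`),
never 0. Score ties are broken by template identifier by default; a
pessimistic `ties = "worst"` policy is available for conservative
reporting. Rates are reported as percentages and printed to one decimal.

`specificity_sensitivity_curve()` follows the benchmark's vocabulary:
*specificity* is the fraction of predicted positives that are true
positives (elsewhere called precision) and *sensitivity* the fraction of
true positives predicted positive. `auc_score()` is the rank-based
Wilcoxon-Mann-Whitney area, ties counting one half. `evaluate_scores()`
assembles the per-level Top-1/Top-5 table, pooled and per-level curves,
and the pooled AUC; per-level positive counts can be read off either
ordered direction of a pair, and reports carry the ordered-pair counts
as generated.

## The synthetic generator

`simulate_fold_data()` exists so the whole stack can be exercised without
external databases. It emulates three things:

1. **Hierarchy** — `fold_sim_config()` enumerates a balanced
   class/fold/superfamily/family tree (default 2×2×2×2 = 16 domains, 240
   ordered pairs) with valid sccs codes.
2. **Features** — half the features (by default) are informative:
   Gaussian with unit noise and a mean shift per relationship, FAMILY 1.5,
   SUPERFAMILY 1.0, FOLD 0.5, NONE 0, so separability decays with
   evolutionary distance; the rest are pure noise. The two orderings of a
   domain pair get independent draws, as alignment-derived features are
   not symmetric in practice.
3. **TM-scores** — scaled Beta draws with means 0.65 / 0.52 / 0.42 / 0.30
   per relationship and concentration 30, chosen so the same-fold and
   different-fold distributions overlap substantially in the ambiguous
   0.30-0.50 band while preserving the expected ordering. A degenerate
   `tm_concentration = Inf` returns the location exactly, which the tests
   exploit.

What the generator does **not** emulate: the marginal distributions and
inter-feature correlations of real alignment scores, compositional biases,
unbalanced family sizes, or any sequence-level signal. Passing the
synthetic-recovery experiments therefore demonstrates that the training,
ensembling and evaluation machinery is correct and leak-free — not that
the defaults would reach any particular accuracy on real benchmark data.

## Numerical choices and degenerate inputs

* **Best-epoch parameters.** Trainers keep the epoch-end parameters with
  the lowest full-training-set loss (initialization included), so the
  reported end-of-training loss can never exceed the initial loss even if
  a fixed learning rate overshoots late in training.
* **Mini-batch remainder.** The final short batch of each epoch is used
  as-is; batches are formed after a seeded shuffle each epoch.
* **Cross-entropy clamping.** Probabilities are clamped to
  `[1e-12, 1 - 1e-12]` inside the loss only; the gradient uses the exact
  sigmoid-cross-entropy delta, which is stable without clamping.
* **Regressor initialization scale.** The uniform `[-0.5, 0.5]` weight
  initialization is part of the regressor's definition, but with wide
  inputs (say 84 scaled features feeding 100-unit layers) the initial
  outputs and gradients are large and fixed-rate SGD can diverge; the
  trainer then aborts with a diagnostic rather than returning NaNs.
  Either narrow the architecture or lower `init_range` in
  `dnfoldr_control()`; the package's own 84-feature examples use a
  `F-32-16-1` regressor for this reason.
* **Degenerate targets.** All-negative (or all-positive) label vectors
  train fine and push predictions to the matching side of 0.5; AUC and
  the curves refuse or flag single-class inputs instead of returning a
  misleading number.
* **Problem sizes.** The package's own experiments are sized for a
  single desktop core: recovery experiments use 16-36 domains (240-1260
  pairs), F = 84 features, and the regression experiment 2000 pairs. The
  same code paths scale to the millions of pairs of the real benchmarks;
  only wall time changes.

## Known limitations

* Feature generation from raw sequences (the alignment-tool chain that
  produces the 84 pairwise features) and structural alignment itself are
  out of scope; features and TM-scores are consumed as precomputed
  columns.
* The random-forest partner of the meta-combiner is consumed as an
  external score column, not trained here.
* Training is plain R matrix arithmetic on CPU; no GPU path.
* No significance testing or bootstrap intervals on the success rates.
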