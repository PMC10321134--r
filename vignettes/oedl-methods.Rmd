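---
title: "Methods: optimized stacked deep ensembles for three-class prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optimized stacked deep ensembles for three-class prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

`oedl` models three-class clinical prognosis (the motivating setting is
acute ischemic stroke, with discharge-NIHSS bands A < 1, B 1–4, C ≥ 5) from
two tabular feature blocks: a small set of mixed-type clinical variables
and a wide block of continuous radiomics-style image features. The
challenges are the ones typical of that setting: a few hundred samples,
marked class imbalance (roughly 106:289:46), hundreds of partly redundant
candidate features, and the wish to fuse the two modalities.

The package implements the full workflow as composable stages —
simulate/load → impute → filter → encode → standardize → select → fuse →
split → balance → fit → evaluate — with a strict rule that every fitted
parameter (imputation pools, variance estimates, one-hot level sets,
standardization moments, importance rankings, correlation prunes,
resampling) is learned from training rows only. Where the original
experimental protocol is ambiguous on that point, fidelity flags
(`select_on_all`, `balance_before_split`) reproduce the laxer ordering
with loud warnings.

## Preprocessing

**Imputation.** Missing continuous cells are filled with a multiple Monte
Carlo estimate: the mean over `M = 5` repetitions of the mean of `N = 20`
draws with replacement from the feature's observed training values — an
empirical-bootstrap mean of means. The sampling distribution is the
feature's own empirical distribution because the method statement ("many
independent random samples of the expectation") does not commit to a
model, and the bootstrap is the simplest reading that needs none.
Categorical cells take the modal observed category. Missingness is treated
as MCAR and, in the generator, restricted to clinical continuous features
(machine-extracted radiomics features are complete in practice).

**Variance filter.** Continuous features pass only if their *population*
(divide-by-n) variance on raw training values exceeds a threshold
(default 0.3). The estimator is fixed and documented so that boundary
cases are deterministic: `{0,1,0,1}` has population variance 0.25 and is
removed at threshold 0.3. Categorical features bypass the filter.

**Encoding and scaling.** Categorical features expand to a full n-level
indicator block (no reference level dropped), giving a partition of unity
per parent feature; indicator columns stay on their 0/1 scale.
Continuous features are z-scored with training means and population SDs.
"Normalization" and "standardization" are sometimes conflated in this
literature; the transformation implemented is the z-score, which is what
the defining formula states.

**Splitting.** The train/test split stratifies by label percentage: each
class contributes round-half-up(`train_frac` × class size) training rows,
the largest-remainder allocation between the two shares. On the default
441-sample cohort at 0.7 this yields train 74/202/32 and test 32/87/14.

## Feature selection and fusion

Radiomics features pass an embedded dual-booster funnel. Two
gradient-boosting configurations score every feature:

* a **leaf-wise** (best-leaf-first) boosted tree ensemble, scored by total
  split gain; and
* a **depth-wise second-order** boosted tree ensemble, scored by split
  count ("weight").

Both are run via xgboost (leaf-wise via its `lossguide` grow policy) on a
single thread for determinism. The selection rule is
`(top-50(A) ∩ top-50(B)) ∪ top-10(A) ∪ top-10(B)`: features strongly
supported by both scorers plus the very best of each. This set-algebra
reading reproduces the characteristic shrinkage pattern (dozens of pooled
candidates collapsing to ~20 survivors) of the protocol it implements.
Survivors then pass a greedy Pearson prune at |r| > 0.9: scanning in
descending importance, any candidate too correlated with an already-kept
feature is dropped. Keeping the higher-importance member is deterministic;
a seeded random-keep mode exists for fidelity with protocols that retain
"a random one". Clinical features skip the booster funnel and receive only
the correlation check before encoding. Fusion is column-wise concatenation
aligned by sample id, with modality metadata preserved.

## Class balancing

Training data (only) can be rebalanced by random over/undersampling,
SMOTE, or SMOTEENN. SMOTE synthesizes minority points as `p + u (q − p)`
for a minority point `p`, one of its k = 5 same-class Euclidean nearest
neighbours `q`, and `u ~ U(0,1)`, equalizing counts to the majority. ENN
then removes every point whose class disagrees with the majority vote of
its k = 3 nearest neighbours, votes computed once on the post-SMOTE set
(a single prune pass, no iteration). Distances are measured on the
standardized one-hot representation; interpolated indicator values are
left fractional because the learners consume them numerically. Vote and
distance ties break by class order and row index, so the whole stage is
deterministic given the seed.

## Base learners

Three deep learner families share one `fit`/`predict_proba` contract, all
trained with softmax cross-entropy and Adam (first-moment decay 0.9 — the
"momentum 0.9" convention — and fixed batch size 20) under seeded
minibatch shuffling, so training is bit-reproducible on one machine.

* **DNN** — fully connected ReLU stack. The hidden activation is
  configurable (the defining per-neuron equation leaves σ unspecified);
  ReLU is the default.
* **LSTM-RNN** — a stack of LSTM cells followed by a fully connected
  softmax head. Tabular rows have no temporal axis, so by default the
  feature vector enters as a **single time step**; a features-as-timesteps
  mode (`input_mode = "feature_steps"`) is provided behind a flag. Neither
  shaping is claimed to be the original study's, which does not state one.
  The cell uses the standard gate recurrences; backpropagation through
  time is exact (verified against numerical gradients in the test suite).
* **DBN** — greedy layer-wise pretraining of restricted Boltzmann
  machines by CD-1 (one Gibbs step; the protocol names no k), then
  supervised fine-tuning of the unrolled sigmoid stack by backprop. The
  first RBM uses Gaussian visible units because binary RBMs cannot model
  z-scored inputs; deeper layers are Bernoulli. The energy and joint
  probability follow E(v,h) = −b'v − c'h − h'Wv with Z by summation, and
  the tests verify Σ p(v,h) = 1 by exhaustive enumeration on small
  machines.

## Stacking and voting

Stacking uses T = 5 stratified folds (the ambiguous phrase "50%
cross-validation" is read as 5-fold; the fold count is configurable):
for each family, every training row is scored by a model whose fold was
held out, and the concatenated class probabilities (3 classes × 3
families = 9 meta-features) train a 100-tree random-forest meta-learner.
Probabilities rather than hard labels are used as meta-features — the
richer signal, since the algorithm sketch leaves the type open. Base
families are refit on the full training set for test-time inference
(standard stacking practice; the sketch's test path is ambiguous between
refit and fold-averaging). Hard voting takes the modal label with ties
broken by class order; soft voting takes the argmax of the mean
probability. EDL denotes the stack with default architectures; OEDL the
stack after per-family architecture search.

## BBOA architecture search

The big bang optimization algorithm is a PSO-family integer metaheuristic:

* **Chaotic initialization.** Each galaxy's initial coordinates come from
  iterating the sinusoidal map m′ = a·m²·sin(πm) (a = 2.3) from a seed
  integer in [0,100] scaled to (0,1), then mapping affinely into the
  search box and rounding integer dimensions. The published update
  formulas print the affine map with swapped bounds; the implementation
  uses lower + m·(upper − lower), the only form that maps [0,1] into the
  box.
* **Velocity update.** v ← w_w·v + ef1·r1·(pbest − x) + ef2·r2·(gbest − x)
  with fresh per-dimension uniforms, then clamping at 0.2 of each
  dimension's range (the clamp prevents integer-rounding oscillation; the
  source is silent). The printed equations repeat the personal best in
  both attraction terms; the personal/global reading implemented here is
  the one consistent with the accompanying symbol table and prose. ef1 =
  ef2 = 2.0, w_s = 0.9, w_e = 0.4 follow PSO-literature conventions, as
  the source gives no numbers.
* **Adaptive inertia.** w_w = w_s − (w_s − w_e)·t/T, exactly w_s at t = 0
  and w_e at t = T.
* **Greedy elitism.** Personal and global bests are replaced only on
  strict improvement, so the best-so-far history is monotone.

For architecture search the position vector is
[n_layers, neurons_1 … neurons_Lmax] with n_layers ∈ [1, L_max] and
neurons ∈ [1, 100]; unused layer slots are ignored when decoding, and
positions decoding to the same architecture are evaluated once (memoized).
The fitness is validation macro-F1 (the objective is never named in the
source; accuracy is available) on an inner 80/20 stratified split carved
from the training data — the optimizer never sees test rows. Search
evaluations run at a reduced epoch budget; the winning architecture is
refit at the full budget.

## Evaluation

The 3×3 confusion matrix is read one-vs-rest per class. ACC is total TP
over total (TP + FP) — algebraically trace/total. Macro precision and
recall are unweighted class means; a zero-denominator class contributes 0
with a warning. Macro-F1 is the harmonic mean of macro-P and macro-R
(not the mean of per-class F1 — the defining formula composes the
macros). ROC curves sweep thresholds over each class's distinct
probability values plus infinite endpoints; AUC is the trapezoid area,
which under grouped ties equals the Mann–Whitney statistic with half
credit per tie (the tie convention needed for constant scores to give
exactly 0.5). Macro-AUC is the unweighted mean of per-class AUCs; a class
absent from the truth raises an error unless explicitly skipped.

## The synthetic cohort generator

`synth_config()` defaults encode the study conditions the pipeline
assumes: 441 samples in proportions 106:289:46, 17 clinical features
(about one-third continuous lab-value-like variables, the rest
categorical with 2–4 levels, echoing an OCSP-type and lesion-position
variable), 200 continuous radiomics-style features, MCAR missingness at
5% on clinical continuous cells. Continuous features are class-conditional
Gaussians with unit within-class SD; informative features receive
class-mean contrasts of `effect_size` SD; informative categoricals are
multinomials tilted toward a class-specific modal level. Redundant blocks
are noisy copies of an informative leader at correlation `block_corr`
(leader–member r = ρ, member–member r = ρ², matching the redundancy the
Pearson prune is meant to remove). Class counts follow largest-remainder
rounding, so the default cohort reproduces 106/289/46 exactly.

The default `effect_size = 0.6` SD places single deep learners in the
mid-80s test-accuracy range on the default cohort — the difficulty regime
the method-comparison tables of interest report — so that ensemble and
balancing effects are probed where they matter rather than at a ceiling.
The split-signal variant partitions the class signal across modalities
(clinical separates A from {B,C}; radiomics separates C from {A,B}) so
that neither modality alone can resolve all three classes but the fusion
can.

What the generator does *not* emulate: real radiomics marginals (heavy
tails, boundedness, feature-family structure), informative missingness,
label noise, and inter-feature correlations beyond the planted blocks.
Passing tests therefore demonstrate algorithmic correctness and
qualitative orderings under the stated statistical structure, not
clinical performance.

## Problem sizes and numerical choices

Desk-scale runs use the reduced profile: 60 training epochs at learning
rate 1e-3 (scaling the rate up as the epoch budget scales down from the
full profile's 1000 epochs at 1e-4), CD pretraining 5 epochs, BBOA with
5 galaxies × 4 iterations over L_max = 2 layers and a 20-epoch search
budget. The ordering experiments run the default 441-sample cohort with
5 seeds and report medians. The full profile reproduces the original
training regime and is exposed via `profile = "full"` and the BBOA
configuration.

Numerical conventions collected in one place: population variance/SD
throughout; softmax with row-max subtraction; cross-entropy clipped at
1e-12; Adam (β1 = 0.9, β2 = 0.999, ε = 1e-8); k-NN distance ties by row
index; vote and argmax ties by class order A < B < C; all randomness
drawn from named per-stage generators derived from one integer seed.

## Known limitations

* Training is single-threaded base R; the full 1000-epoch profile on
  hundreds of samples takes minutes per learner, not seconds.
* The LSTM's forget gate receives no gradient in single-step mode (its
  term multiplies a zero initial cell state); this is inherent to the
  single-step reading of tabular data.
* ENN is a single pass; repeated editing until fixpoint is deliberately
  out of scope.
* Hybrid balancing is not uniformly beneficial. On the default generator,
  where the majority class is geometrically intermediate between the two
  minority classes, the post-SMOTE ENN vote removes a large share of
  original majority rows (roughly 45% at the default settings), reversing
  the imbalance; with leakage-safe train-only balancing this costs
  macro-F1 relative to no balancing (the acceptance script reports the
  signed difference as `smoteenn_minus_none_macro_f1`). Protocols that
  balance the pooled data before splitting let synthetic points reach the
  test set and will rate hybrid balancing far more favourably; the
  `balance_before_split` fidelity flag reproduces that ordering, with a
  warning, for comparison purposes.
* The generator's categorical signal model (tilted multinomials) is
  simple; selection operates mainly on the continuous radiomics block.
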