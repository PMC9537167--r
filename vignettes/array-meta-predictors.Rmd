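---
title: "Methods: array-type meta-predictors for CWA-likeness detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array-type meta-predictors for CWA-likeness detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`dtiarray` implements a stacked, two-stage classifier for
chemical-warfare-agent (CWA) likeness.

Stage one learns drug–target interactions (DTI): for each of five
cholinergic targets (nAChR, mAChR, AChE, BuChE, VAChT) a binary
classifier `f = L(T, w)` maps a 1024-bit circular fingerprint to an
active/inactive call, where `T` is the target's cleaned activity set
and `L` one of four learners (RF, DT, SVM, KNN). Ten seeds control ten
independent stratified 70:30 train/test divisions, giving the
5 × 4 × 10 grid of 200 models.

Stage two treats the 200 predictions for one compound as an ordered
array (a "meta-predictor"): slot order is fixed — target slowest, seed
middle, algorithm fastest — and the flat vector is refilled row-major
into `[50×4]`, `[40×5]`, `[5×10×4]` or `[10×5×4]`. A small CNN
`g = CNN(f_ij, w')` learns the CWA/nonCWA discrimination from these
arrays. The core assumption is chemo-centric: structurally similar
molecules share pharmacology, so the *pattern* of predicted cholinergic
activity is informative about nerve-agent-like mechanism even for
compounds with no measured endpoint.

Because the canonical flat order is refilled row-major into every
layout, the flat 200-vector *is* the row-major flattening of each
shape; reshaping is metadata-only and therefore lossless by
construction (the tests verify the materialized roundtrip
independently). For 3D shapes the leading axis enters the CNN as input
channels.

## Data cleaning and binarization

`read_activity_csv()` consumes the 11-column ChEMBL-export layout.
Rows are dropped (and counted, reason by reason) when the unit is not
nM, the standard value is missing or negative, the target cannot be
mapped to the closed five-target set, the relation symbol is not one of
`=, <, >, <=, >=`, or the SMILES does not parse. `deduplicate()`
collapses repeated (compound, target) measurements to their median — a
robust choice given that public potency duplicates often span orders of
magnitude — keeping the relation only when all duplicates agree.

`binarize()` calls a compound active when potency ≤ `threshold_nM`.
The threshold is **not** a literature constant of this method; the
default 10,000 nM (10 µM) is the conventional DTI cutoff and is
exposed as a parameter. Censored records are resolved only when the
censoring direction settles the call (`> v` with `v ≥` threshold →
inactive; `< v` with `v ≤` threshold → active); anything else is
dropped and counted rather than guessed.

## Fingerprints

ECFP (connectivity invariants) and FCFP (pharmacophoric feature
invariants) at diameters 0/2/4/6 (Morgan radius = diameter/2), folded
to a fixed 1024 bits — 8 configurations per run. Folding collisions are
accepted as-is. Chemistry is delegated to RDKit through a bundled batch
helper on the session's `python`; the package never parses SMILES
itself. Which configuration feeds the final models is a run parameter
(default ECFP, diameter 4); `fp_config_grid()` supports sweeping all
eight.

## Learners

No CRAN tree/SVM package is assumed present, so the four learners are
implemented in-package behind one contract — every model exposes a
continuous positive-class score in [0, 1]:

* **DT**: CART with gini impurity on binary features (max depth 16,
  minimum split 5); leaf class frequency is the score.
* **RF**: bagging of 50 such trees with per-node feature subsampling
  (`mtry = floor(sqrt(p))`, minimum split 2); score = mean of tree
  scores.
* **SVM**: exact C-SVM dual (radial kernel) solved with `quadprog`;
  `gamma` defaults to `1/(p·mean feature variance)`, cost 1. Scores are
  Platt-calibrated (logistic fit on the decision values with
  regularized targets) to satisfy the probability contract.
* **KNN**: fraction of positives among the k = 5 nearest training
  fingerprints (`FNN` k-d tree).

Hyperparameters are deliberately library-default-like and exposed; the
method's contribution is the grid and the meta-stage, not tuned base
learners. Determinism: DT/KNN are bit-reproducible; RF/SVM are
reproducible given the seed, which controls both the data division and
the learner's internal sampling.

## Ensemble-AUC and model selection

"Ensemble-AUC" is used for best-model selection but has two defensible
readings; both are implemented in `ensemble_auc()` and the choice is a
config flag:

* `mean_seed` (default): each seed's model scores its own held-out 30%
  and the seed-wise ROC-AUCs are averaged. This respects the "ten
  differently divided data" design and needs no common test set.
* `averaged_prob`: the seed models' probabilities are averaged on one
  common evaluation set, and a single AUC of the averaged score is
  reported.

Selection (`select_best()`): per (target, algorithm) the best seed is
the arg-max of held-out ROC-AUC; per target the best algorithm is the
arg-max of ensemble-AUC; ties break by higher held-out MCC, then lower
seed index / canonical algorithm order. Two AUC notions are kept
strictly apart everywhere: `auc_balanced = (TPR + TNR)/2`
(threshold-based balanced accuracy) and the ranking `auc_roc`
(Mann–Whitney, ties counted one half). Both are reported side by side
because published tables of this design are ambiguous about which is
meant.

## Metrics: numerical choices

* Zero-denominator rates are reported `NA` and listed in `undefined`,
  never silently 0.
* ROC-AUC is computed from midranks (ties = ½ win), verified in the
  tests against an exhaustive pair-counting oracle up to n = 50.
* AUPR is average precision (step integral, tie blocks collapsed to a
  single threshold) — no linear interpolation, which is optimistic on
  PR curves.
* The loss is exactly
  `-(1/(m+n)) [Σ log f(x⁺) + Σ log(1 − f(x⁻))]` with probabilities
  clipped at ε = 1e-7.

## Meta-arrays and sampling regimes

`predict_meta()` requires a complete grid and refuses a fingerprint
configuration differing from the grid manifest. Binary encoding
thresholds each score at 0.5; the `{1, 2}` slot-value convention is
supported as `binary12` (an affine shift — it changes nothing about
learnability, only matches the published convention); `probability`
keeps raw scores. The slot order is version-pinned by a hash; persisted
arrays or grids from a different ordering are rejected at load.

Sampling regimes: Model 01 native; Model 02 removes duplicate arrays
(first occurrence kept; identical arrays with *conflicting* labels are
all kept and flagged as collisions rather than silently resolved);
Model 03/04 apply SMOTE to Model 01/02. SMOTE synthesizes
`x + u·(neighbour − x)` with a single `u ~ U(0,1)` per synthetic point
among k = 5 minority neighbours (the algorithm's canonical default) and
leaves values continuous — re-thresholding would collapse synthetics
onto existing binary points. Synthetic rows carry a `synthetic` flag.

**Leakage policy.** The meta-level 70:30 split happens *before* any
oversampling; `split_arrays()` refuses datasets already containing
synthetic rows, and `evaluate_detector()` refuses evaluation sets with
any synthetic row. The early-stopping monitor is a stratified 20% of
the training portion. (Whether the original design resampled before or
after its split is not documented; splitting first is the only choice
that keeps the held-out metrics honest, so the package enforces it.)

## The CNN and MLP baseline

Published architectural details beyond "convolutional, pooling,
flatten, dense" live in an unavailable supplement, so the default stack
is the smallest standard one satisfying that description: conv(32
filters, 3×3, same padding, ReLU) → max-pool (2×2 where the spatial
dims allow, else 2×1, remainders dropped) → flatten → dense(64, ReLU) →
dense(2, softmax). Fixed training protocol: Adam, learning rate 0.01,
batch 32, at most 100 epochs, early stopping on validation loss with
patience 10 and best-weight restore. The loss optimized is the printed
binary cross-entropy (the tests assert the training-loop loss equals
the metrics-module formula). The implementation is plain R linear
algebra (im2col convolution), which at 200-slot inputs is faster than
any backend round-trip and bit-reproducible from the seed.

The MLP baseline replaces each conv/pool block by a dense(128, ReLU)
layer, keeping the trainable-layer count equal to the CNN's, and trains
under the identical protocol.

Degenerate inputs: single-class training data abort training;
single-class evaluation sets flag ranking metrics undefined; non-finite
training states abort with a divergence diagnostic.

## The synthetic world

The generators produce the *statistical shape* the pipeline assumes,
not chemistry:

* **DTI sets** (`gen_dti_dataset`): per target a disjoint block of 15
  planted bits; actives carry each planted bit with probability 0.85
  (inactives 0.15); the clean label is the majority vote of the planted
  bits; the observed label flips with probability `activity_noise`
  (default 0.1). Background bits fire at density 0.05, matching the
  sparsity of real 1024-bit fingerprints. Class-conditional planted
  bits were chosen because a majority over *independent* fair bits is
  near-parity and unlearnable at n = 500 — while real actives of a
  target genuinely share substructures. Defaults were fixed from
  design-stage simulations before the acceptance thresholds were ever
  measured.
* **Noise semantics.** Label-flip noise caps agreement with the
  *observed* labels at 1 − noise (Bayes bound; a test asserts learners
  respect it at noise 0.2). Signal *recovery* is therefore measured
  against the clean pre-flip labels, which the generator attaches as
  `y_clean`; the end-to-end acceptance criterion asserts per-target
  clean-label ROC-AUC > 0.9 — achievable precisely because flip noise
  is independent of the features.
* **Meta stage** (`gen_meta_stage`): a latent five-target activity
  profile per compound; P(CWA) = 0.9 if active on AChE *and* BuChE,
  else 0.02 — the cholinesterase conjunction mirrors the nerve-agent
  mechanism narrative without touching real agent structures. Class
  sizes default to 95/3126 (the reference imbalance); rejection
  sampling hits the counts exactly. Arrays can also be synthesized
  directly with a per-slot fidelity parameter (1.0 = faithful slots,
  0.5 = pure noise), which is how the no-signal null (AUPR ≈
  prevalence) is tested.
* **Tiny SMILES set**: 40 embedded innocuous drug-like structures for
  smoke-testing the chemistry path. Deliberately, nothing CWA-like is
  embedded or generated anywhere.

What a green suite does establish: the formulas match independent
oracles; the slot bookkeeping, reshape and resampling contracts hold;
and the full pipeline recovers a planted signal end to end. What it
does not establish: performance on real ChEMBL/CWA/NPS data (the
synthetic world has no folding collisions shared across targets, no
activity cliffs, no assay heterogeneity, and its class imbalance is
milder in the reduced test configuration), nor that the published
headline numbers are reproducible — those require the external
database.

## Known limitations

* The SVM dual is solved densely; fine to a few thousand training
  compounds per model, not beyond.
* Platt calibration on training decisions can be optimistic on tiny
  sets.
* The CNN is CPU-scale by design; no GPU path.
* `auc_balanced` vs ranking AUC ambiguity in the source design is
  documented, not resolved; both are always reported.
* The published ensemble-AUC is never formally defined there; the
  default here (seed-mean) is a declared choice.
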