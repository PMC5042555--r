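---
title: "Methods: the litclass TF-IDF classification pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the litclass TF-IDF classification pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litclass)
```

`litclass` is a single-machine pipeline in the classic biomedical
literature-classification style: bag-of-words TF-IDF features over stemmed
unigrams and bigrams, three classifiers stated in their primal forms, and
repeated k-fold cross-validation. This vignette records the model, the
parameter choices, the numerical decisions, and what the synthetic-data
tests do and do not establish.

## Preprocessing

Raw text goes through a fixed chain: (1) lower-casing and replacement of
every character outside `a-z0-9` and whitespace by a space; (2) tokenization
on whitespace runs; (3) stop-word removal against a bundled, versioned
English list (a user list can be substituted); (4) an *optional*,
default-off pass collapsing runs of three or more identical characters; and
(5) Porter stemming.

Decisions worth making explicit:

* **Hyphens are punctuation.** `p53-mediated` tokenizes as `p53`,
  `mediated`. The hyphen seen inside bigram feature names
  (`cancer-surviv`) is the join character added during n-gram extraction,
  never a surviving text hyphen.
* **Digits are token characters**, so gene symbols (`p53`, `brca1`, `her2`)
  survive; tokens containing digits bypass the stemmer.
* **Stemmer variant.** We implement Porter's 1980 algorithm plus the
  author's two later published step-2 refinements (`bli → ble`,
  `logi → log`, the latter measured so that `biology → biolog`). The
  algorithm is deliberately *not* made idempotent: stripping a suffix can
  expose another (`proliferation → prolifer`, whose stem re-stems to
  `prolif`); this is a documented property of the algorithm, and the
  vocabulary is built from single-pass stems.
* **Duplicate-character collapsing** (step 4) is an ambiguous preprocessing
  notion (duplicate tokens? character runs?); it is provided as an opt-in flag
  (`collapse_repeats = TRUE`) and is off by default, which is safest for
  scientific prose (`coooool → col` only when asked).
* **Sentence boundaries** are not tracked: bags of words are unaffected by
  them, and bigrams are taken over the whole token stream. A window that
  respects sentence boundaries would change a negligible fraction of
  bigrams at abstract scale.
* Rare-word removal happens at vocabulary construction (post-stemming), via
  `min_df`.

## Features

For document `d` and term `t` (a stem or a hyphen-joined stem pair), the
feature value is `W(t,d) = TF(t,d) · log10(N / DF(t))` with raw counts as
`TF` — no length normalization and no L2 scaling of the vectors; the raw
count is what makes the weighting's arithmetic legible (a term with
`TF = 56` and `DF = N` still weighs exactly 0). Two
consequences are load-bearing and tested: `W = 0` iff `TF = 0` or
`DF = N`, and `W` is strictly monotone in `TF` (increasing) and `DF`
(decreasing).

The vocabulary — term set, positions (lexicographic, hence reproducible) and
document frequencies — is always built on the **training portion only**;
test documents are vectorized against it and unseen terms are dropped. This
avoids test-set leakage through the IDF. `min_df = 2` operationalizes
"rare words removed": a term must appear in at least two training documents.

## Classifiers

All three classifiers consume the same TF-IDF vectors.

* **Multinomial naive Bayes** treats feature values as pseudo-counts:
  `P(t | c) ∝ (Σ_{d∈c} W(t,d)) + λ` with Laplace smoothing `λ = 1`;
  priors are class proportions; prediction is the arg-max joint
  log-likelihood, with posteriors normalized by log-sum-exp. Fractional
  "counts" are intentional — the pipeline has a single feature
  representation — and the implementation is tested against an exhaustive
  enumeration oracle on tiny fixtures.
* **Linear SVM and logistic regression** minimize
  `f(w) = a·R(w) + (1/n) Σ L(w; x_i, y_i)` with hinge or logistic loss and
  `R ∈ {0, ‖w‖₁, ½‖w‖₂²}` by full-batch subgradient descent: step
  `γ_t = step_size/√t`, L2 folded into the subgradient, L1 applied by
  soft-thresholding after each step, weights initialized at zero (so equal
  configurations give bit-identical weights; subsampling via
  `minibatch_fraction < 1` is seeded). Defaults — 100 iterations, step size
  1.0, `a = 0.01`, L2 — pin the long-documented Spark MLlib 1.x defaults
  for these components, making "default parameters" concrete and
  reproducible.
* **No intercept** by default, matching the `z = wᵀx` decision rule; a
  constant bias feature can be appended by the caller if needed. The
  positive outcome is `z > 0`, equivalent to thresholding `σ(z)` at 0.5 for
  the logistic model. (One sometimes sees the rule written `wᵀx > 0.5`,
  which conflicts with thresholding the probability at 0.5; we threshold
  the probability, i.e. `z` at 0.) Ties (`z = 0`) go to the negative/pivot
  class.
* **Multiclass** is one-vs-rest for the linear models (arg-max decision
  score, exact ties to the lexicographically smallest label) and native for
  naive Bayes.

## Evaluation protocol

`cross_validate()` runs repeated k-fold cross-validation (defaults
`k = 5`, `repeats = 10`, repetition `r` seeded with `seed + r − 1`): per
fold, the vocabulary, IDF and model are rebuilt on the training folds and
metrics are computed on the held-out fold, so every fold trains on 80% of
the corpus and tests on the remaining 20%. Folds are stratified by class by
default (a small balanced corpus keeps fold metrics stable; unstratified
splitting is available). Both five and ten repetitions are common choices
for this protocol; repeats is a parameter, default 10.

Metrics come from confusion counts (`ACC = (TP+TN)/(P+N)`,
`PPV = TP/(TP+FP)`, `TPR = TP/(TP+FN)`); undefined ratios are reported as
`NA` with a warning, never silently as 0. Multiclass precision/recall are
macro-averaged over one-vs-rest reductions (micro available). ROC curves and
trapezoidal AUC come from threshold sweeps (computed through pROC, verified
in tests against exhaustive Mann–Whitney pair counting); per-classifier ROC
scores are the decision score `z` (SVM), `σ(z)` (logistic) and the class
posterior (naive Bayes).

## The synthetic corpus generator

`generate_corpus()` emulates the structure the pipeline assumes: classes
that differ in the frequency of class-specific vocabulary. Each document
draws its content tokens from the mixture
`(1 − s)·shared + s·own-class-terms`, where

* the **shared vocabulary** (default 500 pronounceable pseudo-words)
  follows a Zipf distribution, so near-ubiquitous terms exercise the
  TF-IDF down-weighting of uninformative words;
* each class has a disjoint **discriminative vocabulary** (default: ten
  plausible clinical terms per cancer type);
* **signal `s`** is the probability mass on own-class terms. `s = 0` makes
  class-conditional distributions identical (accuracy must fall to chance);
  `s = 0.5`, the default study condition, is deliberately well-separated;
* document length is negative-binomial (mean 150 tokens ≈ abstracts;
  dispersion 10; a mean of ~3000 would emulate full text);
* stop-words (rate 0.25) and attached punctuation (rate 0.1) are injected
  so preprocessing is genuinely exercised, and the corpus round-trips
  through the JSONL/CSV formats.

What passing tests on this generator show: the pipeline recovers planted
class structure (10×5-fold mean accuracy ≥ 0.90 for all three classifiers at
`s = 0.5`, 600 documents), collapses to chance under label permutation
(mean accuracy within a binomial band around 1/3), and improves
monotonically with `s`. What they do not show: performance on real PubMed
corpora — real abstracts have correlated vocabulary, class imbalance,
polysemy and citation boilerplate that the generator does not model, so
absolute accuracies here do not transfer.

`generate_blobs()` supplies low-dimensional Gaussian fixtures for the
linear-model unit tests (separability by construction when the inter-mean
distance dwarfs `sigma`).

## Numerical and edge-case decisions

* `train_test_split` rounds the training size half-up and shuffles with the
  given seed; same seed, same split.
* Fold sizes differ by at most one; stratified folds deal each class
  round-robin with a carried offset so remainders do not pile onto fold 1.
* `tfidf_weight` errors on the contradictory input `df = 0, tf > 0`.
* Sparse vectors store strictly positive weights only; the dimension is
  carried so vectors stay "equal-length".
* Objective monitoring: the regularized objective is recorded at every
  iteration;
  on convex toy problems it is non-increasing once the step decays (checked
  with tolerance in tests).
* Empty documents are legal (warned at corpus construction) and vectorize
  to all-zero vectors; naive Bayes then falls back to the priors.

## Problem sizes used in the shipped checks

The test suite and behavioral checks use a 600-document synthetic corpus
(3 × 200, signal 0.5, seed 1) for the full 10×5-fold protocol, 60–120
document corpora for module tests, ≤ 6-document fixtures for enumeration
oracles and ≤ 50-point fixtures for AUC pair counting — sizes chosen so the
whole suite runs in a few minutes on one CPU while still exercising every
code path at realistic sparsity.

## Known limitations

* No lemmatization, POS tagging or named-entity recognition; no trigram+
  features, feature hashing or dimensionality reduction.
* Binary logistic regression with OVR, not multinomial softmax; linear
  kernels only.
* The MEDLINE reader ingests `PMID`/`TI`/`AB` fields only; labels come from
  a sidecar file, since MEDLINE records carry MeSH terms rather than task
  labels, and MeSH parsing is out of scope.
* IDF over train+test jointly versus train-only: both conventions exist in
  practice; we chose train-only, the leak-free variant, which can only make
  reported accuracies conservative.
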