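---
title: "Cross-species phenotype translation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species phenotype translation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotrans)
```

## The translation problem

A mouse disease model and a human cohort for the same condition measure
overlapping but non-identical biology. Interpreting the mouse experiment
directly — differential expression on the mouse, homolog-mapped to human
symbols — predicts only the part of the human disease program that the
mouse actually recapitulates. `phenotrans` treats translation as a
*transductive* learning problem instead: the human cohort itself (without
its labels) participates in training, so the model can pick up
human-specific signal that no amount of mouse-only analysis could reach.
The final deliverables are predicted human phenotypes and, downstream of
them, predicted human DEG and enriched-pathway sets.

Everything operates on a `case_study`: a mouse and a human expression
matrix restricted to a shared, identically ordered homolog gene list, each
z-scored by gene on its own samples, each with a two-level phenotype
factor (the second level is treated as the disease class).

## Preprocessing

The fixed order is: collapse duplicate gene rows, restrict to 1:1 homolog
pairs measured in both species, then z-score each cohort independently.

* **Duplicate collapse** keeps, per symbol, the row with the largest mean
  expression over all samples; mean ties keep the first occurrence. This
  is deterministic and stable under row reordering of the ties.
* **Homolog restriction** enforces a 1:1 map by keeping the first-listed
  pair among conflicts (with a warning); gene order follows the human
  dataset. Conflict handling in homology databases is genuinely
  underdetermined; first-listed is the simplest choice that is exactly
  reproducible from the input file.
* **Z-scoring** uses the sample standard deviation (n − 1). Zero-variance
  genes are set to all zeros with a warning rather than erroring: constant
  genes carry no class information, and real cohorts frequently contain
  them. Z-scoring is applied per cohort *after* restriction and never
  across cohorts — pooling mouse and human samples into one standardization
  would leak test-set information into training.
* The test suite asserts idempotence of both collapse and z-scoring, and
  exact round-tripping of the TSV reader/writer pair.

## Feature selection

`select_features()` fits an elastic-net-penalized **binomial** regression
of phenotype on expression (`glmnet`), over a geometric λ path, picking
λ at the minimum mean cross-validated deviance. Choices that were open and
how they were fixed:

* **Family.** The phenotype is binary, so logistic rather than Gaussian
  loss. (A Gaussian lasso on a ±1 coding selects very similar sets on
  z-scored data; logistic is the statistically natural choice.)
* **λ rule.** Minimum-CV rather than the 1-SE rule: more permissive,
  consistent with the large feature sets this style of analysis reports.
* **Folds.** 10-fold, stratified by class, with fold assignment keyed to
  *sorted sample identifiers* under a seed — so permuting the columns of
  the input matrix cannot change any sample's fold, and the selected set
  is invariant to sample order (asserted in tests). When the smaller class
  has fewer samples than the fold count the policy degrades to
  leave-one-out, which is the only workable scheme for the smallest
  model-organism cohorts (4–5 animals per class).
* **Empty selections.** On signal-free data the CV optimum can keep zero
  genes. Downstream training always needs features, so the fallback takes
  the 10 genes with largest absolute class-mean difference and warns
  loudly. The same route handles the degenerate case where every gene has
  zero variance.

The α grid used for benchmarking is {1.0, 0.9, 0.7, 0.5, 0.3, 0.1};
smaller α keeps weakly more genes, a property the tests check as a
majority trend over seeds rather than a per-seed certainty.

## Classifier families and confidence scores

Four families share one contract: a hard label plus a per-sample
confidence in [0, 1] whose only consumer is a *within-batch ranking* (the
merge threshold below), plus a continuous score toward the disease class
for ROC analysis.

| family | model | confidence |
|--------|-------|------------|
| `knn`  | k = 3 nearest by Euclidean distance | fraction of the 3 votes for the winner: 2/3 or 1 |
| `svm`  | linear-kernel maximum margin (`e1071`) | within-batch rank of \|decision value\|, rescaled to [0, 1] |
| `rf`   | 50 bagged trees, √p features per split (`randomForest`) | fraction of trees voting the winner |
| `nn`   | 1 hidden layer of ⌈(p + 2)/2⌉ units, 2 softmax outputs (`nnet`) | larger softmax output |

Notes on the open choices:

* The SVM kernel is linear: few samples in thousands of dimensions is the
  classic linear-kernel regime, and a nonlinear kernel would add a
  hyperparameter the design deliberately fixes. Its confidence is a rank
  transform of the margin distance rather than a fitted probability —
  Platt-style calibration is unstable on cohorts of a handful of samples,
  and only the ranking is ever used.
* KNN distance ties are broken by training-sample order, making
  predictions fully deterministic.
* The network is trained as a batch optimization (BFGS quasi-Newton in
  `nnet`) of the cross-entropy loss on softmax outputs, capped at 500
  iterations with tolerance 1e-6; hitting the cap returns best-so-far
  weights with a warning. With two output nodes the softmax normalization
  is what gives the "confidence = larger output" semantics.
* Random-forest depth is unlimited and only the tree count (50) is fixed;
  these are the conventional defaults for expression data.

## The self-training loop

`translate(cs, family, mode = "semi", alpha, seed)` implements the
iterative augmentation:

1. Iteration 1 selects features and trains on the mouse cohort alone, then
   predicts every human sample.
2. Human samples at or above the 90th percentile of confidence join the
   training set with their predicted pseudo-labels.
3. Iteration *i* ≥ 2 re-selects features on the augmented set (same α and
   CV policy, folds stratified over the augmented labels), retrains,
   re-predicts **all** human samples, and recomputes the merged set at the
   (100 − 10·i)-th percentile.
4. The loop stops at the iteration whose threshold admits every human
   sample — at most 10 iterations — and that iteration's predictions are
   final.

Decisions worth recording:

* **Membership is refreshed, not frozen.** Each iteration's merged set and
  pseudo-labels come from the newest predictions; a sample merged early
  can leave or flip later. Freezing would contradict the re-classification
  of all human samples each round.
* **Percentiles are over all human samples jointly**, not per class, and
  all samples *tied at the cutoff are admitted*. Type-7 quantiles (the R
  default) define the cutoff.
* **The merged count never decreases.** With discrete confidences (KNN
  votes take only the values 2/3 and 1) a tie-heavy iteration can admit
  more samples than the next iteration's percentile would; in that case
  the set is topped up with the next-highest-confidence samples to the
  previous count. This monotone envelope keeps the training set growing
  toward full merger, which is the intent of a descending schedule.
* **Mouse samples are never dropped**, so the training set always contains
  both classes even when every human pseudo-label falls on one side.
* **NN restart guard.** Network training is stochastic; a degenerate first
  fit that throws (almost) all human samples into one class would poison
  every later iteration. Iteration 1 therefore retrains with fresh
  initializations until more than one human sample is predicted into
  *each* class, up to 50 attempts, then proceeds regardless
  (`nn_restart_guard()` is exported and separately tested).
* **Seeds.** Every stochastic step (folds, forest, network init) draws
  from a stream derived arithmetically from the master seed and the
  iteration/attempt number, so a `translation` is exactly reproducible
  from `(case study, family, mode, alpha, seed)`.

`mode = "supervised"` is the one-shot baseline: mouse-only selection and
training, a single prediction pass, a one-row trace.

## Differential expression, pathways, scoring

* `call_degs()`: per-gene two-sided Wilcoxon–Mann–Whitney test between the
  two classes; exact enumeration when the combined n ≤ 12 with no ties,
  otherwise the normal approximation with tie and continuity corrections;
  BH adjustment across genes; significant iff p < 0.05 **and** q < 0.25.
  The joint rule matters: at small n the q cut alone would be porous and
  the p cut alone anti-conservative.
* `enrich()`: one-sided hypergeometric over-representation of the DEG set
  in each GMT gene set, against the *measured-gene* universe (not the full
  annotation — using the annotation universe inflates enrichment for
  platform-dependent reasons). Sets are restricted to measured genes and
  dropped below 3 members; BH across sets; enriched iff q < 0.05, the
  convention of the web enrichment tools this replaces. An empty DEG set
  returns an empty table, not an error.
* `evaluate_translation()` / `evaluate_mouse_direct()`: the predicted
  DEG/pathway sets are scored against the sets derived from the *true*
  human phenotypes via TP/FP/FN set algebra, precision, recall and the
  equal-weight F-score; phenotype-level AUC is the tie-corrected rank
  statistic U/(n₁n₀). A translation that predicts a single class for every
  human sample cannot support a two-group test and is scored with an
  empty predicted DEG set.
* `meta_analyze()`: ordinary least squares of a performance response on
  dummy-coded family, numeric α, and optional design covariates, with
  per-coefficient t-tests; rank-deficient designs error naming the
  collinear columns. A Gaussian linear model is appropriate because the
  response (F-score/AUC) is a bounded continuous summary and only
  direction/significance of effects is interpreted. For claims that one
  family beats another across case studies, `compare_families()` provides
  a paired Wilcoxon signed-rank test as the default comparison.
* `summarize_ci()`: percentile bootstrap (10,000 seeded resamples) for 95%
  intervals of mean scores — no normality assumption on bounded scores.

## The synthetic-data generator

`sim_config()`/`generate_case_study()` draw paired cohorts in which every
pipeline claim is checkable against planted truth. The model: per-gene
Gaussian noise; additive mean shifts of `effect_mouse` / `effect_human`
(in SD units) on the disease-class samples of that species' DEG genes;
three planted gene classes (shared, mouse-only, human-only); an identity
homology map (homology handling is exercised separately on file-based
fixtures); and a pathway collection in which a configurable fraction of
sets draw `deg_pathway_purity` of their members from the human truth DEGs
— each such set is verified hypergeometrically enriched at generation time
and resampled if not, so pathway-level scoring has a self-consistent
truth.

The four named scenarios in `scenario_library()` fix the study conditions:

* **easy_transfer** — 25 shared DEGs, effects 2.5, mouse 20/20, human
  30/30. Translation is easy; used for the no-harm contract (semi vs
  supervised accuracy within 0.05 in the median).
* **divergent** — 6 shared + 20 mouse-only + 40 human-only DEGs, mouse
  effect 2.5, human effect 3.0, mouse 5/5, human 30/30. The small mouse
  cohort mirrors published surgical-sepsis/endotoxemia designs; the
  human-only program dominates the human truth, so direct mouse
  interpretation has recall near 0.1 and zero pathway F-score by
  construction, while a transferable 6-gene core gives the initial
  classifier a foothold. This is the regime in which the self-trained
  network's pathway F-score should exceed the mouse baseline — the
  package's headline mechanism, asserted as a median over 20 seeds.
* **imbalanced_mouse** — a 4/16 mouse cohort: the small-n, high-imbalance
  design regime associated with degraded F-scores; useful as a covariate
  source for `meta_analyze()`.
* **heterogeneous_mouse** — two mouse sub-cohorts (IDs `m1_*`/`m2_*`) each
  expressing the shared core plus its own half of the mouse-only genes: a
  two-strain design.

What the generator does **not** emulate: platform/batch effects,
probe-level noise, correlated gene modules, non-Gaussian intensity
distributions, or label noise. Passing tests on these simulations
therefore demonstrate the *machinery* (contracts, invariants, and the
qualitative mechanism under known truth), not expected performance on any
real cohort pair.

## Problem sizes and numerical choices in the validation suite

The test suite validates statistics against independent oracles
(exhaustive rank-layout enumeration for the WMW test up to n = 10,
brute-force step-up for BH on 1000 random vectors, pairwise-comparison
AUC and direct-formula F-scores on 1000 random instances) and runs the
loop contract on 100 randomized small case studies (60–120 genes, 2–8
human samples per class). Mechanism and no-harm checks use 20 replicate
simulations of the divergent and easy-transfer scenarios at 300 genes;
planted-truth recovery uses effect 3.0 at 40/40 samples. These sizes were
chosen as the smallest at which the contrasts of interest are
unambiguous; the whole suite runs in a few minutes on one CPU.

## Known limitations

* Confidence scores are comparable only within one prediction batch and
  one family; nothing calibrates them across families, so cross-family
  comparisons should use AUC or F-scores, never raw confidences.
* The loop never drops mouse samples; if the mouse cohort is actively
  misleading (rather than merely incomplete) the augmented set inherits
  that bias.
* With very small human cohorts the percentile schedule degenerates (a
  one-sample cohort merges immediately and the "loop" is a single
  supervised pass).
* The meta-analysis treats grid cells as exchangeable observations; it
  does not model the case-study random effect, which would be the next
  step for a formal analysis across a real benchmark.
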