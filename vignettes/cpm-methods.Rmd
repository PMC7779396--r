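---
title: "Connectome-based predictive modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmr)
```

## The problem and the model

Connectome-based predictive modeling (CPM) asks whether a continuous
behavioural or clinical score — here styled after a clinician-rated
symptom-severity scale with observed mean 40.1, SD 22.3, range 3–95 — can be
predicted, subject by subject, from whole-brain functional connectivity.
The data object per subject is a symmetric node-by-node matrix of Fisher
z-transformed Pearson correlations between regional fMRI time courses,
`z = arctanh(r)`. With an `N`-node parcellation there are `N(N-1)/2`
candidate edges (35,778 for `N = 268`).

The procedure, per training set:

1. **Edge selection.** Spearman's rank correlation between each edge weight
   and the score, keeping edges with two-sided `p < 0.05`. Rank correlation
   is used because severity scores are typically non-normal. Edges split by
   the sign of the correlation into a *positive* and a *negative* predictive
   network; the two sets are disjoint by construction (an edge is one or the
   other, never both).
2. **Summarisation.** Each subject's *network strength* per tail is the sum
   of their Fisher-z weights over that tail's selected edges.
3. **Linear model.** A degree-1 least-squares fit of score on strength
   (slope and intercept), per tail.
4. **Cross-validation.** Leave-one-out: steps 1–3 are repeated with each
   subject held out in turn, and that subject's score is predicted from its
   own strength. Selection *inside* the fold is essential; selecting once on
   the full sample leaks the held-out subject's data into the model and
   inflates apparent performance on pure noise (the package's test suite
   demonstrates this on null cohorts).
5. **Evaluation and inference.** Performance is the Spearman correlation
   between predicted and observed scores. Because LOOCV folds are not
   independent, significance comes from a permutation test: the score/matrix
   correspondence is shuffled and the complete nested procedure re-run, with
   `p = (#{null >= observed} + 1)/(n_perm + 1)`, one-sided toward positive
   performance. At 1,000 shuffles the smallest attainable value is
   `1/1001`, which prints as 0.001.
6. **Anatomy.** The *contributing network* is the set of edges selected in
   every fold. It is summarised as edge counts within and between ten
   macroscale regions and eight canonical networks, node degrees, and the
   top-k highest-degree nodes.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.05 | per-edge two-sided selection p-value (t-approximation) |
| `n_perm` | 1000 | permutation count; p floor is `1/(n_perm+1)` |
| `fd_threshold` | 0.5 mm | scrub volumes with framewise displacement strictly above |
| `rot/trans/mean-FD` | 2°, 2 mm, 0.15 mm | subject exclusion, strict `>`, mean FD pre-scrubbing |
| `band` | 0.01–0.1 Hz | Butterworth band-pass corners (order 2, forward–backward) |
| `cost` | 1 | SVR/SVM regularisation (comparators) |

Spearman p-values use the t-distribution approximation with average-rank
ties: an exact per-edge permutation p is infeasible for tens of thousands of
edges inside every fold, and at the sample sizes involved (n ≥ ~20) the
approximation error is far below the 0.05 decision boundary for all but
hairline cases.

## The synthetic cohort generator

No suitable public cohort ships with the package, so every analysis runs on
synthetic cohorts that emulate exactly the statistical structure the method
consumes:

* **Scores** are drawn from a normal distribution truncated to the
  instrument's range. The parent location is solved numerically so the
  *truncated* mean equals the requested mean (naive truncation of a
  Normal(40.1, 22.3) to [3, 95] would shift the realised mean to ≈ 42);
  the requested `sd` is the parent scale, so the realised spread is
  somewhat below it under asymmetric truncation. An optional skew-normal
  shape parameter is exposed because severity scores are often
  right-skewed; no particular skewness is asserted by default.
* **Edges.** Every edge is `baseline + noise_sd * e` on the Fisher-z scale
  with `baseline = 0.3`, `noise_sd = 0.15` — plausible resting-state
  magnitudes. For a planted edge, `e = rho * s + sqrt(1 - rho^2) * noise`
  with `s` the standardised score, so the population Pearson edge–score
  correlation is `effect_size` by construction while the marginal edge
  distribution is indistinguishable from a null edge. Monte-Carlo checks in
  the test suite confirm the calibration to within ±0.05.
* **Time series.** The generator can alternatively emit node time courses
  where each planted node pair shares a latent signal whose mixing weight
  is `0.3 + 0.2 * effect_size * s`, plus a synthetic framewise-displacement
  trace with a configurable spike fraction, to exercise the scrubbing,
  cleaning, and connectivity path end to end.
* **Determinism.** All randomness flows from one master seed; per-subject
  seeds are derived once up front so each subject's draw does not depend on
  generation order.

What the generator does *not* emulate: spatial autocorrelation between
edges, hemodynamics, scanner noise, site effects, or realistic motion
artefacts coupling into the signal. Passing tests therefore certify the
*procedure* — selection, nesting, inference, summarisation — not robustness
to the full messiness of real fMRI.

## Numerical choices and degenerate inputs

* Correlations are clipped to `|r| <= 1 - 1e-7` before `arctanh`, so
  perfectly correlated nodes give a large finite weight (≈ 8.41) instead of
  infinity.
* Zero-variance nodes (flat time courses) produce undefined correlations;
  their edges are set to `z = 0` with a warning rather than dropping the
  subject, preserving cohort alignment.
* Motion-rule comparisons are strict (`> 0.5 mm`, `> 2°`, `> 0.15 mm`); a
  subject exactly at a threshold is kept.
* A fold in which a tail selects no edges predicts the training-mean score
  and is counted, not errored: empty selections are a real phenomenon at
  coarse parcellations and must not abort cross-validation.
* Constant strengths (e.g. all-empty selections) make the slope undefined;
  the fit falls back to slope 0 through the mean with a flag.
* Cleaning order is detrend → nuisance regression → band-pass. The order is
  configurable since conventions differ; this default treats filtering as
  the last linear operation so regression residual structure cannot
  reintroduce out-of-band energy.
* Edge sets are indexed against a fixed row-major upper-triangle
  enumeration ((1,2), (1,3), …), so edge indices in files and results are
  stable across runs and machines.

## Performance engineering

Edge selection re-runs inside every fold of every permutation — about
24,000 Spearman scans of all edges for one 199-shuffle test at n = 120.
For tie-free data (continuous weights and scores, the generic case) the
engine exploits two facts: leave-one-out ranks follow from full-sample
ranks by decrementing every rank above the removed subject's, and the rank
moments of a tie-free fold are closed-form constants. The per-fold Spearman
scan then reduces to one inner product per edge, implemented in C++. Tied
data fall back to a pure-R path that re-ranks every fold with average-rank
handling; the two paths are tested for exact agreement, and both against a
brute-force oracle at 1e-10.

## Design decisions taken where the method is underspecified

* Strengths are summed on the Fisher-z scale (the matrices the model is
  built on), not back-transformed r; switchable by transforming inputs.
* The contributing network is the strict intersection of per-fold
  selections.
* Permutations reshuffle scores only; covariates travel with scores.
* The permutation p is one-sided toward positive prediction for both tails.
* The SVR comparator uses the fold's selected edges (both tails pooled) as
  individual standardised features, linear kernel, cost 1. The SVM
  classifier uses all candidate edges, 10-fold stratified cross-validation,
  within-fold standardisation, cost 1, and reports balanced accuracy
  (mean of sensitivity and specificity) with a mean-|weight| edge map.
* Degree ties in node rankings break by ascending node index and are
  flagged.
* The shipped 268-node atlas assigns nodes to the ten macroscale regions
  (46, 41, 39, 36, 27, 25, 21, 17, 9, 7 nodes) and eight canonical networks
  in contiguous blocks; the region counts are the published ones, the
  per-network counts are synthetic placeholders, and the whole table is a
  stand-in for a real node-to-anatomy lookup, which can be supplied as a
  TSV.

## Problem sizes used in the shipped experiments

The test suite and `scripts/acceptance.R` validate at sizes chosen to keep
a full run on one CPU comfortable: oracle equivalence on 20-subject,
10-node cohorts; null calibration on 120-subject, 50-node cohorts with
199-shuffle permutation tests over 30–50 replicates; planted-network
recovery at n = 200 on a 10-node graph (8 planted edges — small enough that
the 5% selection screen contributes well under one false edge to the
fold-intersection on average); the permutation floor at the full 1,000
shuffles. The `analysis/` scripts additionally run the full 268-node,
122-subject emulation once (a LOOCV pass takes seconds; its 199-shuffle
permutation test around ten minutes on one CPU).

## Known limitations

* The generator's independence between edges makes recovery *easier* than
  on real data, where spatially correlated edges produce correlated false
  selections; precision/recall figures are upper bounds.
* LOOCV performance estimates on null data are slightly pessimistically
  biased (predicted values anti-track the held-out mean), a known property
  of cross-validated regression; the permutation test absorbs this because
  the null distribution carries the same bias.
* The negative-tail model is fit and reported symmetrically with the
  positive tail, but with a one-sided positive-direction permutation p;
  two-sided inference would double small p-values.
* k-fold variants of the cross-validation loop are possible through the
  same engine but are not validated here; LOOCV is the canonical scheme.
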