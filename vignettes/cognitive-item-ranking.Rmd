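---
title: "Ranking ADAS-Cog-13 items that predict Alzheimer's disease progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking ADAS-Cog-13 items that predict Alzheimer's disease progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogprog)
library(dplyr)
```

## The problem

The ADAS-Cog-13 is a 13-task cognitive battery scored 0–85 (higher = more
impaired) that is administered repeatedly in longitudinal dementia cohorts
such as ADNI. A clinically useful question is which of its items carry the
signal that a patient's diagnosis is about to advance along
CN → MCI → AD, because a short, targeted subset of tasks saves assessment
time and focuses clinical attention. `cogprog` implements a complete,
reproducible pipeline for that question:

1. **Integration** — join a diagnosis/demographics table and an item-score
   table on patient ID and visit code, removing incomplete rows.
2. **Progression labeling** — per patient, order visits by month and label a
   visit `1` when the diagnosis stage increased since the previous visit,
   `0` otherwise; stage decreases are labelled `-1` and removed.
3. **Class balancing** — SMOTE oversampling of the rare progression class to
   an even class ratio, followed by a seeded row shuffle.
4. **Ensemble item scoring** — information gain, the Pearson chi-squared
   statistic, and ReliefF, each min–max normalized across the 13 items and
   averaged into a composite score.
5. **Ranking and score-drop clustering** — items sorted by composite score;
   the relative drop `(S_i − S_{i+1}) / S_i` between successive items
   delimits clusters wherever it exceeds 30%.
6. **Redundancy filtering** — pairs of items correlated above `|r| = 0.60`
   lose the member with the larger mean absolute correlation.
7. **Subset evaluation** — five derived item subsets are scored with naive
   Bayes, logistic regression, and an information-split decision tree under
   stratified 10-fold cross-validation, with and without demographics,
   reporting accuracy, sensitivity and specificity.

Because the clinical source data sit behind a registration wall, the package
also ships a first-class synthetic-cohort generator so every stage is
testable end to end.

## The labeling model

Diagnoses are encoded CN = 1, MCI = 2, AD = 3. For patient $p$ with visits
$v_1 < v_2 < \dots$ ordered by month ("bl" = month 0, "m06" = month 6, ...),

$$
\text{label}(v_i) = \operatorname{sign}\!\big(d(v_i) - d(v_{i-1})\big),
\qquad \text{label}(v_1) = 0,
$$

where $d$ is the stage digit. Labels are assigned **before** any removal, so
a `-1` row's successor is still compared against that row's original
diagnosis; `-1` rows are removed afterwards. Two consequences worth knowing:

* A two-stage jump (CN → AD between consecutive visits) is labelled `1` and
  counted separately — only one-stage progressions are typical, but a gap in
  retained visits can produce jumps.
* Relabeling an already-finalized dataset is *not* guaranteed to reproduce
  the same labels when regressions were removed (removal can bring a higher
  and a lower stage next to each other). It is idempotent on regression-free
  data, and the test suite pins exactly that property.
* A missing intermediate visit does not block comparison: consecutive
  *retained* visits are compared regardless of calendar gap.

## The scoring ensemble

The three filters view item relevance differently — information gain is an
entropy reduction, chi-squared measures contingency-table departure from
independence, and ReliefF rewards items that separate nearest neighbours of
opposite classes. Their raw scales are incommensurable (bits; a statistic
that grows with $n$; a bounded weight), so each column is min–max normalized
across the 13 items before the unweighted average. Min–max is the unique
choice under which each method's best item scores exactly 1 and its worst
exactly 0, which is also how the shipped reference table behaves.

Numerical choices:

* **Fractional scores.** SMOTE interpolates, so synthetic rows carry
  non-integer item scores. Information gain and chi-squared bin values to
  the nearest integer grid point before counting (items are ordinal integer
  scales); ReliefF consumes them as-is.
* **ReliefF defaults** — all instances sampled, $k = 10$ neighbours,
  Manhattan distance over range-normalized features, no distance weighting.
  Weights are invariant under affine rescaling of any feature.
* **Ties** in any ranking are broken by item-schema order, so results are
  deterministic.
* **Degenerate inputs** — a constant score column normalizes to all zeros
  with a warning; a zero predecessor score defines a 0% drop with a warning.

## Clustering and subsets

Walking the ranking from the top, an item opens a new cluster exactly when
its relative drop from the predecessor exceeds the threshold (default 30%).
Raising the threshold can only merge clusters. The five subsets are: all
items; all items surviving the correlation filter; cluster 1; clusters
1 ∪ 2; and the items common to every method's top three (`"strict"` mode —
a `"frequency"` mode keeping items in a majority of the top-three lists is
also available, since "common top features" is ambiguous; strict is the
default because it is the stronger reading). A strict intersection can be
empty on noisy data, in which case subset 5 is omitted with a warning.
Subsets identical to an earlier one are flagged and skipped during
evaluation.

The correlation filter visits offending pairs in decreasing $|r|$ and
discards the member with the larger mean absolute correlation to the
remaining items. This is the same discard rule as `caret::findCorrelation`,
which the test suite uses as an independent oracle on single-pair cases;
with several pairs above the cutoff the two scan orders can legitimately
diverge.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` produces an ADNIMERGE-like table (RID, VISCODE, DX,
AGE, PTGEN, PTEDUCAT, PTRACCAT, PTMARRY) and an ADAS-like table (RID,
VISCODE2, 13 item columns). Its defaults are fixed study conditions, not
tuning knobs:

* **Visits** every 6 months; each patient has a uniform 1–8 visits,
  emulating attrition; a further 10% of assessment rows are withheld so the
  join genuinely loses observations.
* **Diagnosis trajectories** follow a Markov chain over CN/MCI/AD with a
  9% per-visit progression probability and 2% regression probability.
  Combined with per-patient visit counts this yields a progression-label
  prevalence of about 5% of retained rows — the class imbalance regime the
  method is designed for (the balancing stage then equalizes it).
* **Item scores** are stage-dependent means plus rounded Gaussian noise
  (SD 1.5), clipped to each item's range. Per-stage shifts are calibrated so
  the three word-memory items dominate the class association and the
  composite-score profile reproduces the published reference profile's shape
  (memory items near the top of the normalized scale, orientation/command/
  word-finding a distinct step below, the rest near the floor).
* **Demographics** carry a deliberately small class effect (patients who
  ever progress are on average ~3 years older and slightly more educated),
  so the documented phase-2 improvement when demographics are added can be
  reproduced qualitatively.

It does **not** attempt ADNI's covariance structure, biomarker columns,
113/121-column schemas, or realistic per-item score distributions — the
stage-shift model is an assumption, not a claim about ADNI. Passing tests
therefore demonstrate that the pipeline recovers planted structure under
realistic noise, imbalance and missingness; they are not evidence about any
particular clinical dataset.

## Balancing before cross-validation

SMOTE is applied once, before feature scoring and cross-validation, and the
synthetic rows are shuffled into the dataset. This matches the workflow the
pipeline reproduces, but it is known to be optimistic: synthetic minority
rows derived from a training point can land in a test fold, leaking
information. Fold-internal SMOTE would be the stricter design; the package
keeps the single-pass design for fidelity and documents the caveat here.
Feature scoring on the *unbalanced* data is available via the
`fs_on_balanced = FALSE` pipeline flag.

## Classifier stand-ins

The evaluation uses naive Bayes (`e1071`), unregularized logistic
regression (`stats::glm`), and an information-split, complexity-pruned
decision tree (`rpart`) behind a pluggable registry. These are equivalents
of the Bayesian-network, logistic and C4.5 learners traditionally used for
this task; exact numeric reproduction of any third-party toolkit is a
non-goal — the tested surface is the metric identities, determinism, and
qualitative orderings (separable data ≈ 100%, permuted labels ≈ 50%,
demographics uplift ≥ 0 in the median).

## Problem sizes used by the validation suite

The suite runs the full chain on cohorts of 120–650 patients
(roughly 400–2200 labeled visit rows; about 2000–4000 after balancing):
large enough that the planted memory-item dominance is recovered in ≥ 90%
of 50 seeded replicates and the permutation-null accuracy concentrates
within 45–55%, while the whole suite stays comfortably within a
single-CPU coffee break. The prevalence figure (~5%) was verified against
an independent Monte-Carlo simulation of the visit-count/transition model.

## A worked example

```{r example, eval = FALSE}
library(cogprog)

cohort <- generate_cohort(cohort_config(n_patients = 400, seed = 7))
merged <- integrate_visits(
  drop_incomplete(cohort$merge, c("RID", "VISCODE", "DX")),
  drop_incomplete(cohort$adas)
)
labeled <- label_progression(merged)

balanced <- labeled |>
  select(all_of(c(adas_items(), "dx_progress"))) |>
  smote_oversample(seed = 7) |>
  shuffle_rows(seed = 7)

ranked <- balanced |>
  score_features(seed = 7) |>
  rank_and_drops() |>
  assign_clusters()

autoplot(ranked)

subsets <- derive_subsets(
  ranked,
  removed = correlation_filter(pearson_matrix(balanced)),
  scores = score_features(balanced, seed = 7)
)
evaluate_subsets(balanced, subsets, n_folds = 10, seed = 7) |>
  report_table()
```

Or in one call: `run_pipeline(run_config(), "my_run")`, which writes every
stage artifact plus a manifest of seeds and stage counts.

## Known limitations

* Time-to-progression is not modelled; a progression label says the stage
  advanced by the next retained visit, not when.
* CN → MCI and MCI → AD progressions are pooled into one positive class.
* The single-pass SMOTE design (above) can inflate absolute cross-validation
  metrics; comparisons *between* subsets are less affected.
* Partially scored assessments are removed, not imputed.
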