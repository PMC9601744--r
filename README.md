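# cogprog

Identify which items of the ADAS-Cog-13 cognitive assessment predict
Alzheimer's disease progression in a longitudinal cohort.

The ADAS-Cog-13 scores thirteen cognitive tasks on a 0–85 scale (higher =
more impaired) and is administered every six months in studies such as ADNI.
`cogprog` implements, as a tested and fully reproducible R pipeline, the
complete analysis that turns two raw study extracts — a
diagnosis/demographics table and an item-score table — into a ranked,
clustered list of predictive items and cross-validated classification
results for reduced item subsets:

* **Progression labeling.** Diagnoses CN/MCI/AD are encoded 1/2/3; per
  patient, each visit is labelled `1` if the stage increased since the
  previous visit, `0` otherwise; stage decreases (`-1`) are removed. The
  first visit of every patient is `0`.
* **Class balancing.** Progression visits are rare (~5%), so the minority
  class is SMOTE-oversampled to ~50/50 and the rows are shuffled.
* **Ensemble item scoring.** Each item is scored by information gain,
  the Pearson chi-squared statistic, and ReliefF. Each method's column is
  min–max normalized across the 13 items and the three are averaged:

  score_i = (IG*_i + CST*_i + ReliefF*_i) / 3, with x* = (x − min) / (max − min).

* **Score-drop clustering.** Items are ranked by composite score; the
  relative drop (S_i − S_{i+1}) / S_i between successive items opens a new
  cluster wherever it exceeds 30%.
* **Redundancy filtering.** Item pairs with |r| > 0.60 (Pearson) lose the
  member with the larger mean absolute correlation.
* **Subset evaluation.** Five derived subsets (all items; correlation-
  filtered; cluster 1; clusters 1∪2; per-method top-3 intersection) are
  evaluated with naive Bayes, logistic regression and an information-split
  decision tree under stratified 10-fold cross-validation, with and without
  demographics, reporting accuracy, sensitivity and specificity in percent.

Real ADNI extracts are registration-gated, so the package ships a
first-class synthetic-cohort generator (`generate_cohort()`) emulating the
statistical structure the analysis relies on: 6-month visit codes, Markov
CN→MCI→AD trajectories with rare progression events, integer item scores
rising with stage (memory items most strongly), missing values, and
unmatched-visit attrition. See the methods vignette
(`vignettes/cognitive-item-ranking.Rmd`) for the model, assumptions and
design decisions.

## A worked example

```r
library(cogprog)
library(dplyr)

cohort  <- generate_cohort(cohort_config(n_patients = 400, seed = 7))
labeled <- integrate_visits(
  drop_incomplete(cohort$merge, c("RID", "VISCODE", "DX")),
  drop_incomplete(cohort$adas)
) |>
  label_progression()

balanced <- labeled |>
  select(all_of(c(adas_items(), "age", "pteducat", "ptgen",
                  "ptraccat", "ptmarry", "dx_progress"))) |>
  encode_demographics() |>
  smote_oversample(seed = 7) |>
  shuffle_rows(seed = 7)

ranked <- balanced |>
  score_features(seed = 7) |>
  rank_and_drops() |>
  assign_clusters()
ranked
#>             item avg_score rank drop_pct cluster
#> 1      WORDRECOG    0.9619    1       NA       1
#> 2     WORDRECALL    0.9588    2    0.317       1
#> 3      DELAYWORD    0.9207    3    3.975       1
#> 4       WORDFIND    0.4411    4   52.089       2
#> 5         NAMING    0.3238    5   26.594       2
#> ...
```

The three word-memory items form cluster 1: the labeled cohort of 1366
visit rows (67 progressions, balanced to 2598 rows) concentrates its class
signal there, and the 52% drop to the fourth item delimits the cluster.
Deriving and evaluating the subsets:

```r
subsets <- derive_subsets(
  ranked,
  removed = correlation_filter(pearson_matrix(balanced)),
  scores  = score_features(balanced, seed = 7)
)
evaluate_subsets(balanced, subsets, n_folds = 10, seed = 7) |>
  report_table() |>
  filter(subset == "subset3")
#>    subset          classifier accuracy_no_demo accuracy_demo sensitivity_no_demo ...
#> 1 subset3           bayes_net            67.63         65.28               77.06
#> 2 subset3 logistic_regression            67.36         72.52               69.67
#> 3 subset3       decision_tree            85.49         87.68               86.61
```

`subset3` is the three memory items; the decision tree classifies
progression at 85.5% accuracy from those three tasks alone and improves to
87.7% when demographics are added — the qualitative pattern the pipeline is
designed to surface. `autoplot(ranked)` draws the score-drop elbow plot and
`tidy()`/`glance()` methods give broom-style access to every result table.

The whole chain is also available as one call,

```r
run_pipeline(run_config(), "my_run")
```

which writes `labeled.csv`, `balanced.csv`, `rank_table.csv`,
`subsets.json`, `table7.csv`, a DSM-5 annotation sheet and a manifest of
seeds and per-stage row counts, or from the shell via
`inst/scripts/cogprog.R <simulate|run>`.

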