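# wearday

Objective data logging from smartphone-connected hearing aids records, for
every user, how many minutes the aids were used in each hour of each day.
`wearday` is an R package for analysing such longitudinal wear-time logs
end to end: it cleans raw per-ear logs into a day-by-hour matrix, describes
the amount of daily use and its variability, discovers *typical days of
use* by clustering hourly profiles, segments *users* on the proportions of
day types they experience, and validates that segmentation with a
supervised classifier ensemble. Because real logging data of this kind is
proprietary, the package also ships a synthetic cohort generator with full
ground truth, so every stage is testable and the whole analysis is
reproducible from code alone.

It is aimed at hearing-healthcare researchers and data scientists working
with device usage logs (or any comparable hour-resolved adherence data),
and is written tidyverse-style: tibbles in, tibbles out, `tidy()`,
`glance()` and `autoplot()` methods on every fitted object.

## The analysis in brief

* **Preprocessing.** Per-ear hourly logs are resolved binaurally (larger
  value per hour); use during temporary disconnections is imputed from
  on-device minute counters — full-time use is assigned directly, on-off
  use is spread evenly over the window (60 min across 2 h → 30 min/h);
  days then pass five filters (no on-off disconnection longer than 2 h, no
  hour above 60 min, at least 60 min of use, hours 6:00–23:59 only, users
  with at least 10 retained days). The result is the matrix **A** (days ×
  18 hours, entries in [0, 60] min).
* **Amount of use.** Per-user mean daily hours and within-user SD;
  light/medium/heavy segments split at the quartiles of user means; pooled
  t-tests with Cohen's d contrast segment variability; a no-intercept
  quadratic y = b₁x + b₂x² relates within-user SD to mean use and peaks at
  −b₁/(2b₂).
* **Day types.** k-means++ on A with the cluster count chosen from the
  WSS/TSS elbow curve (sharpest marginal-gain kink below a 0.5 threshold),
  silhouette and PCA diagnostics, per-cluster IQR-fence outlier trimming
  on distance to centroid, rule-based naming (full day / afternoon /
  sporadic evening), and a weekend-association test (chi-squared +
  Cramér's V).
* **User groups.** Matrix **B** (users × day-type proportions) is
  clustered four ways — k-means, Ward/Euclidean, average-linkage on
  correlation distance, and a density-based hierarchical method
  (implemented in full here) that marks sparse users as noise; mean
  silhouette, Davies–Bouldin and Calinski–Harabasz pick the winner by
  majority of metric wins.
* **Validation.** Matrix **D** (users × average day) feeds a multinomial
  ridge regression, gradient-boosted trees (100 trees, depth 5) and an
  18–128–64–32–c ReLU network (Adam, 25 epochs) on a stratified 80/20
  split over four classes (three groups + noise); majority vote with
  best-classifier tie-break; accuracy, micro/macro one-vs-rest ROC-AUC and
  gain-based hour importances are reported.

## Worked example

```r
library(wearday)

cohort <- generate_cohort(cohort_config(n_users = 300, seed = 42))
prep   <- preprocess_logs(cohort$logs, cohort$windows)
days   <- build_day_matrix(prep$days)

elbow <- select_k_elbow(days, k_range = 1:6, seed = 11, n_restarts = 5)
elbow$curve
#> # A tibble: 6 × 2
#>       k wss_tss
#>   <int>   <dbl>
#> 1     1   1.000
#> 2     2   0.584
#> 3     3   0.424
#> 4     4   0.399
#> 5     5   0.385
#> 6     6   0.370
elbow$k
#> [1] 3

model <- elbow$models[[elbow$k]]
model$type_names <- name_day_types(model)
model
#> <day_cluster_model> k = 3, WSS/TSS = 0.424
#>   afternoon            2227 days,   8.8 h/day
#>   sporadic_evening     2364 days,   3.6 h/day
#>   full_day             3451 days,  12.7 h/day
```

The elbow curve flattens sharply after k = 3 (the drop 3→4 is a tenth of
the drop 2→3), and the three centroids are the expected day shapes: a
~12.7 h full day, a ~8.8 h afternoon day, and a ~3.6 h sporadic evening
day. Continuing to user segmentation and validation:

```r
keep <- trim_cluster_outliers(days, model)
day_labels <- tibble::tibble(user_id = days$user_id, date = days$date,
                             type_name = model$type_names[model$labels],
                             kept = keep)
B   <- build_user_proportions(day_labels, keep = day_labels$kept)
res <- cluster_user_cohort(B, seed = 11)
res
#> <user_cluster_result> winner: hdbscan
#> # A tibble: 4 × 4
#>   method          silhouette davies_bouldin calinski_harabasz
#>   <chr>                <dbl>          <dbl>             <dbl>
#> 1 kmeans               0.518          0.667              318.
#> 2 hac_ward             0.488          0.728              285.
#> 3 hac_correlation      0.508          0.672              307.
#> 4 hdbscan              0.575          0.567              336.
#>   noise users: 28

D <- build_average_day(days, keep)
D <- D[match(B$user_id, D$user_id), ]
report <- validate_clusters(D, res$winner_labels, seed = 7)
report
#> <ensemble_report> best individual classifier: gradient_boosted_trees
#> # A tibble: 4 × 4
#>   classifier             accuracy auc_micro auc_macro
#>   <chr>                     <dbl>     <dbl>     <dbl>
#> 1 multinomial_regression     82.4     0.950     0.919
#> 2 gradient_boosted_trees     88.2     0.971     0.936
#> 3 feedforward_network        84.3     0.967     0.932
#> 4 ensemble                   86.3     0.973     0.936
#>   top boosted-tree features: h9, h8
```

The density-based method wins all three internal metrics (higher
silhouette and Calinski–Harabasz, lower Davies–Bouldin), labelling 28 of
the users as noise; the ensemble predicts a held-out user's group from
their average day with 86% accuracy, and the most informative hours sit in
the mid-morning — exactly where the full-day and afternoon archetypes
diverge. `run_pipeline(pipeline_config(...))` performs all of the above in
one call, writes CSV/JSON stage outputs, and content-hashes every stage
into a reproducibility manifest; `autoplot()` on the fitted objects draws
the centroid curves, elbow curve, group profiles and importances.

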