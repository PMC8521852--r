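#' Configuration for a full pipeline run
#'
#' Bundles every tunable of the analysis chain with its default: the
#' synthetic-cohort settings, the day-clustering controls (candidate k
#' range, elbow threshold, restarts), the user-clustering technique list
#' and minimum-cluster fraction, and the validation split.
#'
#' @param cohort A [cohort_config()].
#' @param k Day-type cluster count, or `"auto"` for elbow selection.
#' @param k_range Candidate k values for the elbow (contiguous from 1).
#' @param elbow_ratio Marginal-gain threshold of [select_k_from_curve()].
#' @param n_restarts k-means++ restarts.
#' @param methods User-clustering techniques to evaluate.
#' @param user_k Cluster count for the non-density user techniques.
#' @param min_cluster_frac Minimum cluster size fraction for the density
#'   technique.
#' @param silhouette_subsample Row cap for day-level silhouette profiles.
#' @param clustering_seed,split_seed Seeds for clustering and for the
#'   train/test split.
#' @param train_frac Training fraction of the validation split.
#' @param out_dir Optional directory; when set, stage outputs are written
#'   as CSV/JSON.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            k = "auto", k_range = 1:6, elbow_ratio = 0.5,
                            n_restarts = 10L,
                            methods = c("kmeans", "hac_ward",
                                        "hac_correlation", "hdbscan"),
                            user_k = 3L, min_cluster_frac = 1000 / 15905,
                            silhouette_subsample = 2000L,
                            clustering_seed = 11L, split_seed = 7L,
                            train_frac = 0.8, out_dir = NULL) {
  structure(
    list(
      cohort = cohort, k = k, k_range = k_range, elbow_ratio = elbow_ratio,
      n_restarts = n_restarts, methods = methods, user_k = user_k,
      min_cluster_frac = min_cluster_frac,
      silhouette_subsample = silhouette_subsample,
      clustering_seed = clustering_seed, split_seed = split_seed,
      train_frac = train_frac, out_dir = out_dir
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys match the arguments of [pipeline_config()]; the `cohort`
#' key holds [cohort_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, raw$cohort %||% list())
  raw$cohort <- NULL
  do.call(pipeline_config, c(list(cohort = cohort), raw))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate, preprocess, usage statistics, day-type clustering
#' (with elbow selection, outlier trimming, naming, weekday association),
#' user clustering (all techniques, internal scores, winner selection) and
#' ensemble validation, in order. Each stage's output is content-hashed
#' into the run manifest, so re-running with an identical configuration
#' reproduces identical hashes and any nondeterminism is detectable.
#'
#' @param config A [pipeline_config()].
#' @return A `wearday_run`: all stage outputs plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- run_stage("simulate", generate_cohort(config$cohort))
  prep <- run_stage("preprocess", preprocess_logs(cohort$logs, cohort$windows))
  days <- build_day_matrix(prep$days)

  use_summary <- run_stage("stats", cohort_use_summary(days))
  var_fit <- run_stage("stats", fit_variability_curve(use_summary$users))

  day_stage <- run_stage("cluster-days", {
    if (identical(config$k, "auto")) {
      elbow <- select_k_elbow(days, config$k_range,
                              ratio_threshold = config$elbow_ratio,
                              seed = config$clustering_seed,
                              n_restarts = config$n_restarts)
      model <- elbow$models[[elbow$k]]
      curve <- elbow$curve
    } else {
      model <- cluster_days(days, k = as.integer(config$k),
                            seed = config$clustering_seed,
                            n_restarts = config$n_restarts)
      curve <- tibble::tibble(k = model$k, wss_tss = model$wss / model$tss)
    }
    model$type_names <- name_day_types(model)
    keep <- trim_cluster_outliers(days, model)
    sil <- silhouette_profile(days, model$labels,
                              subsample = config$silhouette_subsample,
                              seed = config$clustering_seed)
    assoc <- weekday_association(model$type_names[model$labels], days$date)
    list(model = model, curve = curve, keep = keep,
         silhouette_mean = mean(sil$silhouette), association = assoc)
  })
  day_labels <- tibble::tibble(
    user_id = days$user_id, date = days$date,
    cluster = day_stage$model$labels,
    type_name = day_stage$model$type_names[day_stage$model$labels],
    kept = day_stage$keep
  )

  user_stage <- run_stage("cluster-users", {
    B <- build_user_proportions(day_labels, keep = day_labels$kept)
    result <- cluster_user_cohort(
      B, methods = config$methods, k = config$user_k,
      min_cluster_frac = config$min_cluster_frac,
      seed = config$clustering_seed
    )
    list(B = B, result = result)
  })

  report <- run_stage("validate", {
    D <- build_average_day(days, keep = day_labels$kept)
    D <- D[match(user_stage$B$user_id, D$user_id), , drop = FALSE]
    validate_clusters(D, user_stage$result$winner_labels,
                      train_frac = config$train_frac,
                      seed = config$split_seed)
  })

  group_sizes <- table(user_stage$result$winner_labels)
  manifest <- list(
    stages = c("simulate", "preprocess", "stats", "cluster-days",
               "cluster-users", "validate"),
    hashes = list(
      logs = rlang::hash(cohort$logs),
      days = rlang::hash(days),
      day_labels = rlang::hash(day_labels),
      user_labels = rlang::hash(user_stage$result$labels),
      report = rlang::hash(tidy(report))
    ),
    counts = list(
      users_in = nrow(cohort$users),
      days_in = prep$audit$n_input,
      days_retained = prep$audit$n_retained,
      days_kept_after_trim = sum(day_labels$kept),
      users_clustered = nrow(user_stage$B),
      day_k = day_stage$model$k,
      winner = user_stage$result$winner,
      group_sizes = as.list(group_sizes)
    )
  )

  run <- structure(
    list(
      config = config, cohort = cohort, days = days, audit = prep$audit,
      use_summary = use_summary, variability_fit = var_fit,
      day_model = day_stage$model, elbow_curve = day_stage$curve,
      day_silhouette_mean = day_stage$silhouette_mean,
      weekday = day_stage$association, day_labels = day_labels,
      B = user_stage$B, user_result = user_stage$result,
      report = report, manifest = manifest
    ),
    class = "wearday_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.wearday_run <- function(x, ...) {
  cat("<wearday_run>\n")
  cat("  days retained:", x$manifest$counts$days_retained, "of",
      x$manifest$counts$days_in, "\n")
  cat("  day types: k =", x$day_model$k,
      paste0("(", paste(x$day_model$type_names, collapse = ", "), ")"), "\n")
  cat("  user clustering winner:", x$user_result$winner, "\n")
  cat("  ensemble accuracy:", sprintf("%.2f%%", x$report$ensemble$accuracy),
      "\n")
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Writes the stage artefacts (`days.csv`, `audit.json`,
#' `use_summary.json`, `user_summary.csv`, `day_labels.csv`,
#' `day_model.json`, `user_labels.csv`, `user_clustering.json`,
#' `validation_report.json`, `manifest.json`) into `dir`.
#'
#' @param run A `wearday_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  utils::write.csv(run$days, file.path(dir, "days.csv"), row.names = FALSE)
  wj(list(rules = run$audit$rules, n_input = run$audit$n_input,
          n_retained = run$audit$n_retained), "audit.json")
  wj(list(
    pooled = run$use_summary$pooled,
    quartiles = as.list(run$use_summary$quartiles),
    cv = run$use_summary$cv,
    segments = run$use_summary$segment_means,
    curve = list(b1 = run$variability_fit$b1, b2 = run$variability_fit$b2,
                 r_squared = run$variability_fit$r_squared)
  ), "use_summary.json")
  utils::write.csv(run$use_summary$users, file.path(dir, "user_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(run$day_labels, file.path(dir, "day_labels.csv"),
                   row.names = FALSE)
  wj(list(
    k = run$day_model$k, type_names = run$day_model$type_names,
    centroids = run$day_model$centroids, curve = run$elbow_curve,
    silhouette_mean = run$day_silhouette_mean,
    weekday_association = run$weekday
  ), "day_model.json")
  utils::write.csv(run$user_result$labels, file.path(dir, "user_labels.csv"),
                   row.names = FALSE)
  wj(list(scores = run$user_result$scores, winner = run$user_result$winner,
          groups = run$user_result$summary), "user_clustering.json")
  wj(list(
    classifiers = tidy(run$report), best = run$report$best_kind,
    auc_per_class = as.list(run$report$auc_per_class),
    importance = as.list(run$report$importance)
  ), "validation_report.json")
  wj(run$manifest, "manifest.json")
  invisible(dir)
}
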