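#' Build the user-by-day-type proportion matrix
#'
#' Represents each user by the proportion of their retained, typed days
#' falling in each day type — the substrate for user clustering. Days
#' dropped by the per-cluster outlier trim are excluded from the
#' denominators; users left with no retained days are dropped (recorded in
#' the `"dropped_users"` attribute).
#'
#' @param day_labels Tibble with `user_id` and a day-type column.
#' @param keep Optional logical keep-mask aligned with `day_labels` rows
#'   (e.g. from [trim_cluster_outliers()]).
#' @param type_col Name of the day-type column (default `"type_name"`).
#' @return Tibble with `user_id` and one `p_<type>` column per day type;
#'   each row sums to 1.
#' @export
build_user_proportions <- function(day_labels, keep = NULL,
                                   type_col = "type_name") {
  all_users <- unique(day_labels$user_id)
  if (!is.null(keep)) {
    stopifnot(length(keep) == nrow(day_labels))
    day_labels <- day_labels[keep, , drop = FALSE]
  }
  types <- sort(unique(day_labels[[type_col]]))
  counts <- table(day_labels$user_id, day_labels[[type_col]])
  counts <- counts[, types, drop = FALSE]
  prop <- counts / rowSums(counts)
  out <- tibble::as_tibble(as.data.frame.matrix(prop), .name_repair = "minimal")
  names(out) <- paste0("p_", types)
  out <- dplyr::bind_cols(tibble::tibble(user_id = rownames(counts)), out)
  dropped <- setdiff(all_users, out$user_id)
  attr(out, "dropped_users") <- dropped
  out
}

proportion_matrix <- function(B) {
  if (is.data.frame(B)) {
    m <- as.matrix(B[grep("^p_", names(B), value = TRUE)])
    rownames(m) <- B$user_id
    m
  } else {
    B
  }
}

#' Cluster users on their day-type proportions
#'
#' Four techniques are available, mirroring common practice for behavioural
#' segmentation on compositional features:
#'
#' * `"kmeans"`: k-means with k-means++ seeding (exactly `k` clusters);
#' * `"hac_ward"`: hierarchical agglomerative clustering, Euclidean
#'   distance, Ward's method, cut at `k`;
#' * `"hac_correlation"`: agglomerative clustering with Pearson-correlation
#'   distance and average linkage, cut at `k`;
#' * `"hdbscan"`: density-based hierarchical clustering on correlation
#'   distance; infers the cluster count and labels sparse users as noise
#'   (`-1`). Its minimum cluster size is a fraction of the cohort
#'   (`min_cluster_frac`), so cohorts of any size exercise the same
#'   geometry.
#'
#' @param B Proportion tibble from [build_user_proportions()] (or matrix).
#' @param method One of the four technique names.
#' @param k Cluster count for the non-density methods.
#' @param min_cluster_frac Minimum cluster size for `"hdbscan"`, as a
#'   fraction of the number of users.
#' @param seed Seed for the stochastic methods.
#' @param n_restarts k-means++ restarts.
#' @return Integer label vector, one per user; `-1` marks noise (density
#'   method only).
#' @export
cluster_users <- function(B,
                          method = c("kmeans", "hac_ward", "hac_correlation",
                                     "hdbscan"),
                          k = 3L, min_cluster_frac = 1000 / 15905,
                          seed = 1L, n_restarts = 10L) {
  method <- match.arg(method)
  m <- proportion_matrix(B)
  if (nrow(m) == 0) abort("empty proportion matrix")
  switch(method,
    kmeans = cluster_days(m, k = k, seed = seed, n_restarts = n_restarts)$labels,
    hac_ward = stats::cutree(stats::hclust(dist(m), method = "ward.D2"), k = k),
    hac_correlation = stats::cutree(
      stats::hclust(stats::as.dist(correlation_distance(m)), method = "average"),
      k = k
    ),
    hdbscan = hdbscan_dist(
      correlation_distance(m),
      min_cluster_size = max(2L, round(min_cluster_frac * nrow(m)))
    )
  )
}

#' Internal validation scores for a user clustering
#'
#' Mean silhouette, Davies-Bouldin and Calinski-Harabasz, computed in the
#' Euclidean feature space on non-noise points only.
#'
#' @param B Proportion tibble or matrix.
#' @param labels Cluster labels (`-1` = noise, excluded).
#' @param subsample Silhouette subsample cap.
#' @return One-row tibble `silhouette`, `davies_bouldin`,
#'   `calinski_harabasz`.
#' @export
score_clustering <- function(B, labels, subsample = 5000L) {
  m <- proportion_matrix(B)
  ok <- labels != -1
  m <- m[ok, , drop = FALSE]
  labels <- labels[ok]
  if (length(unique(labels)) < 2) {
    abort("need at least 2 non-noise clusters to score")
  }
  tibble::tibble(
    silhouette = mean(silhouette_profile(m, labels, subsample = subsample)$silhouette),
    davies_bouldin = davies_bouldin(m, labels),
    calinski_harabasz = calinski_harabasz(m, labels)
  )
}

#' Select the winning clustering technique
#'
#' Each metric casts one vote: higher silhouette, lower Davies-Bouldin,
#' higher Calinski-Harabasz. The technique with the most votes wins; a
#' three-way tie is broken by silhouette. The choice does not depend on the
#' order methods were evaluated.
#'
#' @param scores Tibble with columns `method`, `silhouette`,
#'   `davies_bouldin`, `calinski_harabasz`.
#' @return The winning method name.
#' @export
select_method <- function(scores) {
  if (nrow(scores) < 2) abort("need at least 2 scored methods")
  wins <- rep(0L, nrow(scores))
  wins[which.max(scores$silhouette)] <- wins[which.max(scores$silhouette)] + 1L
  wins[which.min(scores$davies_bouldin)] <- wins[which.min(scores$davies_bouldin)] + 1L
  wins[which.max(scores$calinski_harabasz)] <- wins[which.max(scores$calinski_harabasz)] + 1L
  top <- which(wins == max(wins))
  if (length(top) > 1) top <- top[which.max(scores$silhouette[top])]
  scores$method[top]
}

#' Per-group day-type profiles
#'
#' For each non-noise group: size, mean proportion of days in each day
#' type with a normal-approximation 95 percent confidence interval, and
#' the predominant day type (argmax of the mean vector).
#'
#' @param B Proportion tibble (with `p_` columns) or matrix.
#' @param labels Cluster labels (`-1` = noise).
#' @return Tibble with one row per (group, day type): `group`, `n`,
#'   `day_type`, `mean`, `ci_lo`, `ci_hi`, `predominant`. Noise count in
#'   attribute `"n_noise"`.
#' @export
summarize_groups <- function(B, labels) {
  m <- proportion_matrix(B)
  ok <- labels != -1
  groups <- sort(unique(labels[ok]))
  out <- purrr::map_dfr(groups, function(g) {
    mg <- m[labels == g, , drop = FALSE]
    mu <- colMeans(mg)
    se <- apply(mg, 2, sd) / sqrt(nrow(mg))
    tibble::tibble(
      group = g,
      n = nrow(mg),
      day_type = sub("^p_", "", colnames(m)),
      mean = unname(mu),
      ci_lo = unname(mu - qnorm(0.975) * se),
      ci_hi = unname(mu + qnorm(0.975) * se),
      predominant = colnames(m)[which.max(mu)] == colnames(m)
    )
  })
  attr(out, "n_noise") <- sum(!ok)
  out
}

#' Run, score and compare all user-clustering techniques
#'
#' Applies every requested technique to the proportion matrix, scores each
#' with the three internal metrics, picks the winner by majority of
#' metric-wise wins, and summarizes the winner's groups.
#'
#' @inheritParams cluster_users
#' @param methods Techniques to evaluate.
#' @return A `user_cluster_result`: `labels` (tibble `user_id` + one column
#'   per method), `scores`, `winner`, `winner_labels`, `summary`.
#' @export
cluster_user_cohort <- function(B,
                                methods = c("kmeans", "hac_ward",
                                            "hac_correlation", "hdbscan"),
                                k = 3L, min_cluster_frac = 1000 / 15905,
                                seed = 1L) {
  m <- proportion_matrix(B)
  labs <- lapply(methods, function(meth) {
    cluster_users(B, meth, k = k, min_cluster_frac = min_cluster_frac,
                  seed = seed)
  })
  names(labs) <- methods
  scores <- purrr::map_dfr(methods, function(meth) {
    dplyr::bind_cols(tibble::tibble(method = meth),
                     score_clustering(m, labs[[meth]]))
  })
  winner <- select_method(scores)
  lab_tbl <- tibble::as_tibble(labs)
  if (is.data.frame(B)) lab_tbl <- dplyr::bind_cols(B["user_id"], lab_tbl)
  structure(
    list(
      labels = lab_tbl,
      scores = scores,
      winner = winner,
      winner_labels = labs[[winner]],
      summary = summarize_groups(m, labs[[winner]])
    ),
    class = "user_cluster_result"
  )
}

#' @export
print.user_cluster_result <- function(x, ...) {
  cat("<user_cluster_result> winner: ", x$winner, "\n", sep = "")
  print(x$scores)
  n_noise <- attr(x$summary, "n_noise")
  if (!is.null(n_noise) && n_noise > 0) cat("  noise users:", n_noise, "\n")
  invisible(x)
}

#' @method tidy user_cluster_result
#' @export
tidy.user_cluster_result <- function(x, ...) x$summary

#' @method glance user_cluster_result
#' @export
glance.user_cluster_result <- function(x, ...) {
  dplyr::bind_cols(
    x$scores[x$scores$method == x$winner, ],
    tibble::tibble(n_noise = attr(x$summary, "n_noise") %||% 0L)
  )
}

#' Group day-type profile plot
#'
#' Mean proportion of days in each day type per user group, with 95
#' percent confidence intervals.
#'
#' @param object A `user_cluster_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot user_cluster_result
#' @export
autoplot.user_cluster_result <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$day_type, y = .data$mean,
                 fill = factor(.data$group))
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(x = "day type", y = "mean proportion of days",
                  fill = "user group") +
    ggplot2::theme_minimal()
}

#' Best alignment of predicted to reference labels
#'
#' Enumerates permutations of the predicted label set (feasible for the
#' small cluster counts used here) and returns the relabeling maximizing
#' agreement with the reference, together with the achieved agreement among
#' non-noise points.
#'
#' @param reference,predicted Label vectors of equal length; `-1` in
#'   `predicted` is noise and excluded from the agreement rate.
#' @return List: `mapping` (named vector predicted -> reference),
#'   `agreement` (fraction), `relabeled`.
#' @export
match_labels <- function(reference, predicted) {
  stopifnot(length(reference) == length(predicted))
  ok <- predicted != -1
  ref_levels <- sort(unique(reference[ok]))
  pred_levels <- sort(unique(predicted[ok]))
  if (length(pred_levels) > 6) abort("too many clusters to enumerate")
  perms <- perms_of(ref_levels, length(pred_levels))
  best <- NULL; best_agree <- -1
  for (p in perms) {
    agree <- mean(p[match(predicted[ok], pred_levels)] == reference[ok])
    if (agree > best_agree) {
      best_agree <- agree
      best <- p
    }
  }
  mapping <- setNames(best, pred_levels)
  relabeled <- rep(NA, length(predicted))
  relabeled[ok] <- mapping[as.character(predicted[ok])]
  list(mapping = mapping, agreement = best_agree, relabeled = relabeled)
}

# all injective assignments of k slots from pool (k <= length(pool))
perms_of <- function(pool, k) {
  if (k == 0) return(list(character(0)))
  out <- list()
  recurse <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return()
    }
    for (i in seq_along(remaining)) {
      recurse(c(chosen, remaining[i]), remaining[-i])
    }
  }
  recurse(pool[0], pool)
  out
}
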