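#' Cluster days of use with k-means++
#'
#' Partitions the day-by-hour matrix into `k` day types by Lloyd's k-means
#' on squared Euclidean distance, with k-means++ seeding and multiple
#' restarts; the restart with the lowest within-cluster sum of squares
#' (WSS) wins. Features are raw minutes per hour, unscaled: all 18 share
#' the same unit.
#'
#' @param days Day table (`user_id`, `date`, `h6`..`h23`) or bare matrix.
#' @param k Number of clusters; `nrow >= k >= 1`.
#' @param seed Integer seed; results are deterministic given it.
#' @param n_restarts k-means++ restarts.
#' @return A `day_cluster_model`: `k`, `centroids` (k x 18), `labels`,
#'   `sizes`, `wss`, `tss`, and the `(user_id, date)` back-references when
#'   available.
#' @export
cluster_days <- function(days, k, seed = 1L, n_restarts = 10L) {
  m <- if (is.data.frame(days)) day_matrix(days) else days
  if (k < 1) abort("`k` must be >= 1")
  if (nrow(m) < k) abort("fewer rows than clusters")
  set.seed(seed)
  ctr <- colMeans(m)
  tss <- sum((m - matrix(ctr, nrow(m), ncol(m), byrow = TRUE))^2)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_init(m, k)
    km <- suppressWarnings(
      kmeans(m, centers = init, iter.max = 100L, algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  structure(
    list(
      k = k,
      centroids = unname(best$centers),
      labels = unname(best$cluster),
      sizes = as.integer(best$size),
      wss = best$tot.withinss,
      tss = tss,
      index = if (is.data.frame(days)) days[c("user_id", "date")] else NULL
    ),
    class = "day_cluster_model"
  )
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance to the nearest center chosen so far.
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(0, k, ncol(m))
  centers[1, ] <- m[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- rowSums((m - matrix(centers[1, ], n, ncol(m), byrow = TRUE))^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- m[pick, ]
    d2 <- pmin(d2, rowSums((m - matrix(centers[j, ], n, ncol(m),
                                       byrow = TRUE))^2))
  }
  # exact-duplicate centers would break Lloyd; nudge onto distinct rows
  if (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    repl <- sample.int(n, length(dup))
    centers[dup, ] <- m[repl, , drop = FALSE] +
      matrix(rnorm(length(dup) * ncol(m), 0, 1e-6), length(dup))
  }
  centers
}

#' @export
print.day_cluster_model <- function(x, ...) {
  cat("<day_cluster_model> k = ", x$k, ", WSS/TSS = ",
      sprintf("%.3f", x$wss / x$tss), "\n", sep = "")
  nm <- if (!is.null(x$type_names)) x$type_names else paste0("type_", seq_len(x$k) - 1)
  for (i in seq_len(x$k)) {
    cat(sprintf("  %-18s %6d days, %5.1f h/day\n", nm[i], x$sizes[i],
                sum(x$centroids[i, ]) / 60))
  }
  invisible(x)
}

#' @method tidy day_cluster_model
#' @export
tidy.day_cluster_model <- function(x, ...) {
  cent <- tibble::as_tibble(x$centroids, .name_repair = ~hour_cols())
  dplyr::bind_cols(
    tibble::tibble(
      cluster = seq_len(x$k),
      type_name = if (!is.null(x$type_names)) x$type_names else
        paste0("type_", seq_len(x$k) - 1),
      size = x$sizes,
      mean_hours = rowSums(x$centroids) / 60
    ),
    cent
  )
}

#' @method glance day_cluster_model
#' @export
glance.day_cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, wss = x$wss, tss = x$tss, wss_tss = x$wss / x$tss)
}

#' Hourly centroid curves of the fitted day types
#'
#' @param object A `day_cluster_model`.
#' @param ... Unused.
#' @return A ggplot of minutes/hour by clock hour, one line per day type.
#' @method autoplot day_cluster_model
#' @export
autoplot.day_cluster_model <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(hour_cols()),
                        names_to = "hour", values_to = "minutes") |>
    dplyr::mutate(hour = as.integer(sub("^h", "", .data$hour))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$hour, y = .data$minutes,
                                 colour = .data$type_name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "clock hour", y = "use (min/h)", colour = "day type") +
    ggplot2::theme_minimal()
}

#' Pick the elbow of a WSS/TSS curve
#'
#' Formalizes the visual elbow rule as a marginal-gain ratio criterion. For
#' each candidate k, the ratio r_k compares the drop in WSS/TSS gained by
#' adding one more cluster (k to k+1) with the drop gained by the previous
#' one (k-1 to k). Candidates where this ratio falls below
#' `ratio_threshold` are kinks — adding another cluster no longer
#' substantially increases the explained variation — and the sharpest kink
#' (smallest ratio; the earliest in case of ties) is chosen, matching where
#' the eye bends the curve. A flat curve returns k = 1 with a warning; a
#' curve with no qualifying kink returns the largest candidate.
#'
#' @param curve WSS/TSS values for k = 1, 2, ... (non-increasing).
#' @param ratio_threshold Marginal-gain ratio below which a kink qualifies
#'   as an elbow.
#' @return The chosen k.
#' @export
select_k_from_curve <- function(curve, ratio_threshold = 0.5) {
  kk <- length(curve)
  if (kk < 2) return(1L)
  drops <- -diff(curve)                       # drop achieved by k = 2, 3, ...
  if (drops[1] <= 1e-12) {
    warn("flat WSS/TSS curve; returning k = 1")
    return(1L)
  }
  if (kk == 2) return(2L)
  ratios <- drops[-1] / pmax(drops[-length(drops)], 1e-12)  # r_k, k = 2..kk-1
  qual <- which(ratios < ratio_threshold)
  if (length(qual) == 0) return(as.integer(kk))
  as.integer(qual[which.min(ratios[qual])] + 1L)
}

#' Select the number of day types by the elbow method
#'
#' Fits k-means for each candidate k, computes the WSS/TSS ratio curve, and
#' applies [select_k_from_curve()]. The full curve is returned so the choice
#' can be overridden manually.
#'
#' @inheritParams cluster_days
#' @param k_range Contiguous candidate range starting at 1.
#' @param ratio_threshold Passed to [select_k_from_curve()].
#' @return List with `k` (chosen), `curve` (tibble `k`, `wss_tss`), and
#'   `models` (fitted `day_cluster_model` per candidate).
#' @export
select_k_elbow <- function(days, k_range = 1:6, ratio_threshold = 0.5,
                           seed = 1L, n_restarts = 10L) {
  if (k_range[1] != 1 || any(diff(k_range) != 1)) {
    abort("`k_range` must be contiguous and start at 1")
  }
  models <- lapply(k_range, function(k) {
    cluster_days(days, k, seed = derive_seed(seed, k), n_restarts = n_restarts)
  })
  curve <- vapply(models, function(mod) mod$wss / mod$tss, numeric(1))
  list(
    k = select_k_from_curve(curve, ratio_threshold),
    curve = tibble::tibble(k = k_range, wss_tss = curve),
    models = models
  )
}

#' Elbow curve plot
#'
#' @param curve Tibble `k`, `wss_tss` as returned by [select_k_elbow()].
#' @param chosen_k Optional k to highlight.
#' @return A ggplot.
#' @export
plot_elbow <- function(curve, chosen_k = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$wss_tss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters", y = "WSS / TSS") +
    ggplot2::theme_minimal()
  if (!is.null(chosen_k)) {
    p <- p + ggplot2::geom_vline(xintercept = chosen_k, linetype = "dashed")
  }
  p
}

#' Two-component PCA of the day-by-hour matrix
#'
#' Principal components of the centered (not scaled) day vectors, for
#' visualizing days in two dimensions. Sign convention: each loading
#' vector's largest-magnitude entry is made positive, so on typical cohorts
#' PC1 tracks overall daily use and PC2 contrasts morning against
#' afternoon/evening use.
#'
#' @param days Day table or matrix.
#' @return A `day_pca`: `scores` (tibble `PC1`, `PC2`), `loadings`
#'   (18 x 2), `explained` (proportion of variance per component, all
#'   components).
#' @export
project_pca <- function(days) {
  m <- if (is.data.frame(days)) day_matrix(days) else days
  if (nrow(m) < 2) abort("PCA needs at least 2 rows")
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, 1:2, drop = FALSE]
  scores <- pc$x[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      scores = tibble::tibble(PC1 = scores[, 1], PC2 = scores[, 2]),
      loadings = load,
      explained = pc$sdev^2 / sum(pc$sdev^2)
    ),
    class = "day_pca"
  )
}

#' @export
print.day_pca <- function(x, ...) {
  cat(sprintf("<day_pca> PC1 %.1f%%, PC2 %.1f%% of variance\n",
              100 * x$explained[1], 100 * x$explained[2]))
  invisible(x)
}

#' Flag per-cluster outlier days by the IQR fence rule
#'
#' Within each cluster, days whose Euclidean distance to their own centroid
#' falls outside \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\] of that cluster's distance
#' distribution are marked for removal, so atypical days do not dilute the
#' centroid patterns.
#'
#' @param days Day table or matrix the model was fitted on.
#' @param model A `day_cluster_model`.
#' @return Logical keep-mask, one entry per row.
#' @export
trim_cluster_outliers <- function(days, model) {
  m <- if (is.data.frame(days)) day_matrix(days) else days
  stopifnot(nrow(m) == length(model$labels))
  d <- sqrt(rowSums((m - model$centroids[model$labels, , drop = FALSE])^2))
  keep <- rep(TRUE, nrow(m))
  for (cl in seq_len(model$k)) {
    in_cl <- model$labels == cl
    q <- quantile(d[in_cl], c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    keep[in_cl] <- d[in_cl] >= q[1] - 1.5 * iqr & d[in_cl] <= q[2] + 1.5 * iqr
  }
  keep
}

#' Name day-type clusters from their centroid shapes
#'
#' For a three-cluster model the names follow the field's reading of the
#' centroid curves: the cluster with the smallest total use is
#' `sporadic_evening`; of the remaining two, the one with substantial
#' morning (7:00-10:59) use is `full_day` and the other `afternoon`. Any
#' other k gets generic `type_0` ... names. The assignment depends only on
#' the centroids, not on cluster ids.
#'
#' @param model A `day_cluster_model`.
#' @return Character vector of unique names, one per cluster.
#' @export
name_day_types <- function(model) {
  k <- model$k
  if (k != 3) return(paste0("type_", seq_len(k) - 1))
  totals <- rowSums(model$centroids)
  morning <- rowSums(model$centroids[, which(HOURS %in% 7:10), drop = FALSE])
  names_out <- character(3)
  sporadic <- which.min(totals)
  names_out[sporadic] <- "sporadic_evening"
  rest <- setdiff(1:3, sporadic)
  full <- rest[which.max(morning[rest])]
  names_out[full] <- "full_day"
  names_out[setdiff(rest, full)] <- "afternoon"
  names_out
}

#' Association between day type and weekend
#'
#' Pearson chi-squared test of independence on the 2 x k table of
#' weekend/weekday against day type, with Cramer's V
#' (sqrt(chi2 / (n min(r-1, c-1)))) as effect size.
#'
#' @param labels Day-type labels, one per day.
#' @param dates Dates of the same days; weekend = Saturday/Sunday.
#' @return One-row tibble `chi2`, `df`, `p_value`, `cramers_v`, with the
#'   contingency table in attribute `"table"`.
#' @export
weekday_association <- function(labels, dates) {
  weekend <- format(as.Date(dates), "%u") %in% c("6", "7")
  tab <- table(ifelse(weekend, "weekend", "weekday"), labels)
  if (any(dim(tab) < 2)) abort("need both weekend margins and >= 2 day types")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(ct$statistic) / (sum(tab) * min(dim(tab) - 1)))
  out <- tibble::tibble(
    chi2 = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    cramers_v = v
  )
  attr(out, "table") <- tab
  out
}
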