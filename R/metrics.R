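#' Silhouette coefficients
#'
#' For each observation, compares mean distance to its own cluster (cohesion,
#' a) with the smallest mean distance to another cluster (separation, b):
#' s = (b - a) / max(a, b), in \[-1, 1\]. Singleton clusters score 0. For
#' large inputs a random subsample keeps the pairwise-distance matrix
#' tractable; the subsample size is reported in the result.
#'
#' @param x Numeric matrix (or day table with `h6`..`h23` columns).
#' @param labels Integer/character cluster labels, one per row.
#' @param subsample Maximum rows used; `NULL` means all.
#' @param seed Seed for the subsample draw.
#' @return Tibble `idx`, `cluster`, `silhouette` for the (sub)sampled rows.
#' @export
silhouette_profile <- function(x, labels, subsample = NULL, seed = 1L) {
  if (is.data.frame(x)) x <- day_matrix(x)
  stopifnot(nrow(x) == length(labels))
  idx <- seq_len(nrow(x))
  if (!is.null(subsample) && nrow(x) > subsample) {
    set.seed(seed)
    idx <- sort(sample(idx, subsample))
    x <- x[idx, , drop = FALSE]
    labels <- labels[idx]
  }
  labs <- sort(unique(labels))
  if (length(labs) < 2) abort("silhouette needs at least 2 clusters")
  d <- as.matrix(dist(x))
  n <- nrow(x)
  sizes <- as.numeric(table(factor(labels, levels = labs)))
  member <- outer(labels, labs, "==")           # n x k indicator
  sums <- d %*% member                          # total distance to each cluster
  own <- match(labels, labs)
  s <- numeric(n)
  for (i in seq_len(n)) {
    ni <- sizes[own[i]]
    if (ni <= 1) { s[i] <- 0; next }
    a <- sums[i, own[i]] / (ni - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  tibble::tibble(idx = idx, cluster = labels, silhouette = s)
}

#' Davies-Bouldin index
#'
#' Mean, over clusters, of the worst-case similarity to another cluster:
#' (scatter_i + scatter_j) / distance(centroid_i, centroid_j), where scatter
#' is the mean Euclidean distance of members to their centroid. Lower is
#' better.
#'
#' @inheritParams silhouette_profile
#' @return A non-negative scalar.
#' @export
davies_bouldin <- function(x, labels) {
  if (is.data.frame(x)) x <- day_matrix(x)
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2) abort("Davies-Bouldin needs at least 2 clusters")
  cents <- t(vapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]),
                    numeric(ncol(x))))
  scatter <- vapply(seq_along(labs), function(i) {
    xi <- x[labels == labs[i], , drop = FALSE]
    mean(sqrt(rowSums((xi - matrix(cents[i, ], nrow(xi), ncol(x),
                                   byrow = TRUE))^2)))
  }, numeric(1))
  cd <- as.matrix(dist(cents))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (scatter[i] + scatter[j]) / cd[i, j]
    }, numeric(1)))
  }, numeric(1)))
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion, scaled by
#' (n - k) / (k - 1). Higher is better.
#'
#' @inheritParams silhouette_profile
#' @return A non-negative scalar.
#' @export
calinski_harabasz <- function(x, labels) {
  if (is.data.frame(x)) x <- day_matrix(x)
  labs <- sort(unique(labels))
  k <- length(labs)
  n <- nrow(x)
  if (k < 2) abort("Calinski-Harabasz needs at least 2 clusters")
  gmean <- colMeans(x)
  w <- 0; b <- 0
  for (l in labs) {
    xi <- x[labels == l, , drop = FALSE]
    ci <- colMeans(xi)
    w <- w + sum((xi - matrix(ci, nrow(xi), ncol(x), byrow = TRUE))^2)
    b <- b + nrow(xi) * sum((ci - gmean)^2)
  }
  if (w == 0) return(Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Area under the ROC curve (binary)
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random positive scores above a random negative.
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical (or 0/1) true class, `TRUE` = positive.
#' @return AUC in \[0, 1\].
#' @export
auc_binary <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' One-vs-rest multiclass ROC-AUC
#'
#' Binarizes each class, computes per-class AUC from that class's score
#' column, then aggregates: micro-average pools all binarized decisions
#' into one AUC; macro-average is the unweighted mean of the per-class
#' AUCs.
#'
#' @param prob Matrix of class scores, columns named by class.
#' @param truth Vector of true class labels (matching column names).
#' @return List with `per_class`, `micro`, `macro`.
#' @export
multiclass_auc <- function(prob, truth) {
  classes <- colnames(prob)
  stopifnot(!is.null(classes))
  per_class <- vapply(classes, function(cl) {
    auc_binary(prob[, cl], truth == cl)
  }, numeric(1))
  micro <- auc_binary(
    as.vector(prob),
    as.vector(vapply(classes, function(cl) truth == cl,
                     logical(length(truth))))
  )
  list(per_class = per_class, micro = micro,
       macro = mean(per_class, na.rm = TRUE))
}
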