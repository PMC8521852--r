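test_that("user proportions are count ratios on retained typed days", {
  labs <- tibble::tibble(
    user_id = c("u1", "u1", "u1", "u2", "u2"),
    type_name = c("full_day", "full_day", "afternoon", "afternoon", "afternoon")
  )
  B <- build_user_proportions(labs)
  expect_equal(B$p_full_day, c(2 / 3, 0))
  expect_equal(B$p_afternoon, c(1 / 3, 1))
  expect_equal(rowSums(proportion_matrix_test(B)), c(1, 1))

  # trimmed days leave the denominators
  B2 <- build_user_proportions(labs, keep = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(B2$p_full_day[1], 1 / 2)

  # a user with no retained days is dropped and audited
  B3 <- build_user_proportions(labs, keep = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(B3$user_id, "u1")
  expect_equal(attr(B3, "dropped_users"), "u2")

  # row-stochasticity survives user dropping
  expect_true(all(abs(rowSums(proportion_matrix_test(B3)) - 1) < 1e-9))
})

test_that("all four techniques recover perfectly separated blocks", {
  B <- tibble::tibble(
    user_id = sprintf("u%02d", 1:30),
    p_full_day = rep(c(1, 0, 0), each = 10),
    p_afternoon = rep(c(0, 1, 0), each = 10),
    p_sporadic_evening = rep(c(0, 0, 1), each = 10)
  )
  truth <- rep(1:3, each = 10)
  for (meth in c("kmeans", "hac_ward", "hac_correlation", "hdbscan")) {
    labels <- cluster_users(B, meth, k = 3, min_cluster_frac = 0.2, seed = 1)
    expect_equal(match_labels(truth, labels)$agreement, 1)
    if (meth != "hdbscan") expect_false(any(labels == -1))
  }
})

test_that("Ward clustering agrees with a brute-force agglomeration oracle", {
  set.seed(41)
  x <- matrix(c(0, 0, 0.2, 0, 5, 5, 5.3, 5, 10, 10, 10.4, 10), 6, 2,
              byrow = TRUE) + matrix(rnorm(12, 0, 0.01), 6, 2)
  # naive Ward: repeatedly merge the pair with the smallest increase in
  # within-cluster sum of squares
  naive_ward <- function(x, k_stop) {
    clusters <- as.list(seq_len(nrow(x)))
    while (length(clusters) > k_stop) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(clusters)) {
        for (j in seq_len(i - 1)) {
          a <- x[clusters[[i]], , drop = FALSE]
          b <- x[clusters[[j]], , drop = FALSE]
          d <- nrow(a) * nrow(b) / (nrow(a) + nrow(b)) *
            sum((colMeans(a) - colMeans(b))^2)
          if (d < best[1]) best <- c(d, i, j)
        }
      }
      clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
      clusters[[best[3]]] <- NULL
    }
    labels <- integer(nrow(x))
    for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
    labels
  }
  for (k in 2:3) {
    ours <- stats::cutree(stats::hclust(dist(x), "ward.D2"), k = k)
    oracle <- naive_ward(x, k)
    expect_equal(match_labels(oracle, ours)$agreement, 1)
  }
})

test_that("density clustering finds planted groups and flags sparse users", {
  set.seed(42)
  mk <- function(center, n, sd) {
    m <- pmax(matrix(rnorm(n * 3, rep(center, each = n), sd), n, 3), 1e-3)
    m / rowSums(m)
  }
  B <- rbind(mk(c(.6, .2, .2), 400, .07), mk(c(.2, .6, .2), 150, .07),
             mk(c(.2, .2, .6), 200, .07))
  noise <- matrix(rgamma(100 * 3, 1), 100, 3)
  noise <- noise / rowSums(noise)
  X <- rbind(B, noise)
  truth <- rep(c(1, 2, 3, 0), c(400, 150, 200, 100))
  labels <- hdbscan_dist(correlation_distance(X),
                         min_cluster_size = round(0.063 * nrow(X)))
  expect_equal(length(setdiff(unique(labels), -1)), 3)
  expect_gt(sum(labels == -1), 0)
  ok <- labels != -1 & truth != 0
  m <- match_labels(truth[ok], labels[ok])
  expect_gt(m$agreement, 0.95)
})

test_that("correlation distance handles constant rows and bounds", {
  x <- rbind(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2), c(1, 1, 1) / 3)
  d <- correlation_distance(x)
  expect_equal(diag(d), rep(0, 3))
  expect_true(all(d >= 0 & d <= 2))
  expect_equal(d[1, 2], d[2, 1])
  # the constant row sits at distance 1 from everything else
  expect_equal(d[3, 1], 1)
  expect_equal(d[3, 2], 1)
  # perfect anti-correlation is the maximal distance
  expect_equal(d[1, 2], 1 - stats::cor(x[1, ], x[2, ]))
})

test_that("internal scores drive method selection by majority of wins", {
  # one method best on everything wins outright
  s1 <- tibble::tibble(
    method = c("a", "b"),
    silhouette = c(0.9, 0.2), davies_bouldin = c(0.1, 1.2),
    calinski_harabasz = c(100, 10)
  )
  expect_equal(select_method(s1), "a")

  # the published comparison: the density method wins all three
  s2 <- tibble::tibble(
    method = c("kmeans", "hac_ward", "hac_correlation", "hdbscan"),
    silhouette = c(0.4539, 0.4264, 0.6400, 0.7604),
    davies_bouldin = c(0.8267, 0.7169, 0.6001, 0.4176),
    calinski_harabasz = c(18473, 13732, 35802, 70327)
  )
  expect_equal(select_method(s2), "hdbscan")
  # order invariance
  expect_equal(select_method(s2[sample(4), ]), "hdbscan")

  # 2-vs-1 split goes to the majority method
  s3 <- tibble::tibble(
    method = c("a", "b"),
    silhouette = c(0.9, 0.2), davies_bouldin = c(0.1, 1.2),
    calinski_harabasz = c(10, 100)
  )
  expect_equal(select_method(s3), "a")
})

test_that("group summaries report sizes, means, and tight CIs correctly", {
  B <- rbind(matrix(rep(c(0.6, 0.3, 0.1), each = 8), 8),
             matrix(rep(c(0.1, 0.8, 0.1), each = 6), 6))
  colnames(B) <- c("p_full_day", "p_afternoon", "p_sporadic_evening")
  labels <- c(rep(1L, 8), rep(2L, 6), -1L)
  B <- rbind(B, c(1 / 3, 1 / 3, 1 / 3))
  s <- summarize_groups(B, labels)
  expect_equal(sum(unique(s[, c("group", "n")])$n), 14)
  expect_equal(attr(s, "n_noise"), 1)
  # identical rows within a group: zero-width confidence intervals
  expect_equal(s$ci_lo, s$ci_hi, tolerance = 1e-12)
  # predominant type is the argmax of the group mean vector
  expect_equal(s$day_type[s$group == 1 & s$predominant], "full_day")
  expect_equal(s$day_type[s$group == 2 & s$predominant], "afternoon")
})
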