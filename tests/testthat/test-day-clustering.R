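test_that("k-means++ clustering matches construction and WSS oracle", {
  # k = 1: the centroid is the column mean
  set.seed(31)
  x <- matrix(runif(20 * 18, 0, 60), 20, 18)
  m1 <- cluster_days(x, 1, seed = 1)
  expect_equal(as.numeric(m1$centroids), colMeans(x), tolerance = 1e-8)
  expect_equal(m1$wss, m1$tss, tolerance = 1e-8)

  # planted two-cloud partition is recovered exactly
  a <- matrix(rnorm(15 * 18, 5, 1), 15, 18)
  b <- matrix(rnorm(15 * 18, 50, 1), 15, 18)
  m2 <- cluster_days(rbind(a, b), 2, seed = 1)
  expect_equal(length(unique(m2$labels[1:15])), 1)
  expect_equal(length(unique(m2$labels[16:30])), 1)
  expect_false(m2$labels[1] == m2$labels[16])

  # WSS equals brute-force recomputation from labels and centroids
  m3 <- cluster_days(x, 3, seed = 2)
  wss_brute <- sum(vapply(seq_len(nrow(x)), function(i) {
    sum((x[i, ] - m3$centroids[m3$labels[i], ])^2)
  }, numeric(1)))
  expect_equal(m3$wss, wss_brute, tolerance = 1e-6)

  # determinism given the seed
  expect_identical(cluster_days(x, 3, seed = 7)$labels,
                   cluster_days(x, 3, seed = 7)$labels)
  expect_error(cluster_days(x[1:2, ], 3), "fewer rows")
})

test_that("the WSS/TSS curve is non-increasing in k", {
  fx <- small_cohort()
  el <- select_k_elbow(fx$days, 1:5, seed = 3, n_restarts = 3)
  expect_true(all(diff(el$curve$wss_tss) <= 1e-8))
  expect_true(all(el$curve$wss_tss >= 0 & el$curve$wss_tss <= 1 + 1e-8))
})

test_that("the elbow rule picks sharp kinks and handles edge cases", {
  # sharp elbow after the first split
  expect_equal(select_k_from_curve(c(1.0, 0.5, 0.45, 0.44)), 2L)
  # kink at three: second split still substantial, third negligible
  expect_equal(select_k_from_curve(c(1.0, 0.55, 0.30, 0.28, 0.27)), 3L)
  # single candidate
  expect_equal(select_k_from_curve(1.0), 1L)
  # flat curve warns and returns 1
  expect_warning(k <- select_k_from_curve(c(1, 1, 1, 1)), "flat")
  expect_equal(k, 1L)
  # smoothly decaying curve with no kink returns the largest candidate
  expect_equal(select_k_from_curve(c(1, 0.6, 0.38, 0.25, 0.17)), 5L)
})

test_that("PCA components are orthonormal and interpretable", {
  # rank-1 data: one component explains everything
  set.seed(32)
  u <- runif(30); v <- runif(18)
  p1 <- project_pca(outer(u, v))
  expect_equal(p1$explained[1], 1, tolerance = 1e-8)

  fx <- small_cohort()
  p <- project_pca(fx$days)
  expect_equal(unname(crossprod(p$loadings)), diag(2), tolerance = 1e-8)
  # PC1 tracks overall use: loadings share one sign across hours with use
  lead <- p$loadings[, 1][abs(p$loadings[, 1]) > 0.1]
  expect_true(all(lead > 0) || all(lead < 0))
  # PC2 contrasts morning use with use later in the day
  l2 <- p$loadings[, 2]
  morning <- which(6:23 %in% 7:10)
  later <- which(6:23 %in% 11:17)
  expect_true(sign(mean(l2[morning])) != sign(mean(l2[later])))
})

test_that("IQR trimming removes far points and keeps degenerate clusters", {
  base <- matrix(rep(c(rep(30, 9), rep(0, 9)), each = 30), 30, 18)
  far <- matrix(60, 1, 18)
  x <- rbind(base + matrix(rnorm(30 * 18, 0, 0.5), 30), far)
  model <- list(
    k = 1L, centroids = matrix(colMeans(x), 1), labels = rep(1L, 31)
  )
  keep <- trim_cluster_outliers(x, model)
  expect_false(keep[31])
  expect_true(all(keep[1:30]))

  # identical points: IQR 0, everything kept by the closed fences
  same <- matrix(10, 12, 18)
  model2 <- list(k = 1L, centroids = matrix(10, 1, 18), labels = rep(1L, 12))
  expect_true(all(trim_cluster_outliers(same, model2)))
})

test_that("cluster naming follows the centroid shapes and is stable", {
  tpl <- archetype_templates()
  cents <- do.call(rbind, tpl$mean_curve[1:3])
  model <- list(k = 3L, centroids = cents)
  expect_equal(name_day_types(model),
               c("full_day", "afternoon", "sporadic_evening"))
  # permuting cluster ids permutes names consistently
  perm <- c(3, 1, 2)
  model_p <- list(k = 3L, centroids = cents[perm, ])
  expect_equal(name_day_types(model_p),
               c("full_day", "afternoon", "sporadic_evening")[perm])
  # any other k gets generic names
  expect_equal(name_day_types(list(k = 2L, centroids = cents[1:2, ])),
               c("type_0", "type_1"))
})

test_that("weekday association matches the textbook chi-squared formula", {
  # hand-built 2x3 table via labels and dates
  labels <- rep(c("a", "b", "c"), times = c(40, 30, 30))
  dates <- rep(as.Date("2022-01-03"), 100)           # a Monday
  weekend_idx <- c(1:10, 41:60, 71:80)
  dates[weekend_idx] <- as.Date("2022-01-08")        # a Saturday
  res <- weekday_association(labels, dates)
  tab <- attr(res, "table")
  expect_equal(sum(tab), 100)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / 100
  chi2_oracle <- sum((tab - exp_tab)^2 / exp_tab)
  expect_equal(res$chi2, chi2_oracle, tolerance = 1e-12)
  expect_equal(res$cramers_v, sqrt(chi2_oracle / (100 * 1)), tolerance = 1e-12)

  # perfect association has V = 1
  lab2 <- rep(c("a", "b"), each = 10)
  d2 <- rep(c(as.Date("2022-01-08"), as.Date("2022-01-03")), each = 10)
  expect_equal(weekday_association(lab2, d2)$cramers_v, 1, tolerance = 1e-12)
})

test_that("independent labels and dates give a near-zero Cramer's V", {
  set.seed(33)
  ps <- replicate(200, {
    labels <- sample(c("a", "b", "c"), 400, replace = TRUE)
    dates <- as.Date("2022-01-01") + sample(0:27, 400, replace = TRUE)
    res <- weekday_association(labels, dates)
    c(res$p_value, res$cramers_v)
  })
  # p-values roughly uniform: mean near 0.5, no pile-up at 0
  expect_lt(abs(mean(ps[1, ]) - 0.5), 0.1)
  expect_lt(mean(ps[1, ] < 0.05), 0.12)
  expect_lt(mean(ps[2, ]), 0.12)
})
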