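test_that("the average day is the per-user column mean of retained days", {
  days <- day_rows(
    day_row("u1", "2022-01-01", c(60, rep(0, 17))),
    day_row("u1", "2022-01-02", c(0, 60, rep(0, 16))),
    day_row("u2", "2022-01-01", flat_day(9))
  )
  D <- build_average_day(days)
  expect_equal(D$h6, c(30, 30))
  expect_equal(D$h7, c(30, 30))
  expect_equal(as.numeric(D[1, paste0("h", 8:23)]), rep(0, 16))

  # identical days: the average day is that day
  days2 <- day_rows(day_row("u3", "2022-01-01", flat_day(6)),
                    day_row("u3", "2022-01-02", flat_day(6)))
  expect_equal(as.numeric(build_average_day(days2)[1, -1]), flat_day(6))

  # brute-force group-by oracle on random input
  set.seed(51)
  rnd <- dplyr::bind_rows(lapply(1:20, function(i) {
    day_row(sprintf("u%02d", sample(5, 1)), as.Date("2022-01-01") + i,
            runif(18, 0, 60))
  }))
  D3 <- build_average_day(rnd)
  for (u in D3$user_id) {
    expect_equal(
      as.numeric(D3[D3$user_id == u, -1]),
      unname(colMeans(day_matrix(rnd[rnd$user_id == u, ]))),
      tolerance = 1e-12
    )
  }
})

test_that("the train/test split is stratified, disjoint, and exhaustive", {
  labels <- rep(c("a", "b", "c", "d"), each = 25)
  sp <- split_train_test(labels, train_frac = 0.8, seed = 3)
  expect_length(sp$test, 20)
  expect_length(sp$train, 80)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_equal(as.numeric(table(labels[sp$test])), rep(5, 4))
  expect_equal(as.numeric(table(labels[sp$train])), rep(20, 4))

  # deterministic given the seed
  expect_identical(sp, split_train_test(labels, 0.8, seed = 3))

  # frequencies preserved within one user on unbalanced classes
  lab2 <- rep(c("a", "b"), times = c(62, 38))
  sp2 <- split_train_test(lab2, 0.8, seed = 4)
  tr <- table(lab2[sp2$train]) / length(sp2$train)
  expect_true(all(abs(tr - c(0.62, 0.38)) < 0.02))

  expect_error(split_train_test(c("a", "a", "b"), 0.8), "at least 5")
})

test_that("all three classifiers separate a linearly separable toy problem", {
  set.seed(52)
  x <- rbind(matrix(rnorm(40 * 18, 10, 1), 40), matrix(rnorm(40 * 18, 40, 1), 40))
  y <- factor(rep(c("lo", "hi"), each = 40))
  for (kind in c("multinomial_regression", "gradient_boosted_trees",
                 "feedforward_network")) {
    fit <- train_classifier(kind, x, y, seed = 1)
    p <- predict(fit, x)
    pred <- colnames(p)[max.col(p)]
    expect_equal(mean(pred == as.character(y)), 1)
  }
  expect_error(train_classifier("gradient_boosted_trees", x,
                                factor(rep("lo", 80))), "single class")
})

test_that("tree and regression fits are invariant to training row order", {
  set.seed(53)
  x <- matrix(runif(60 * 18, 0, 60), 60)
  y <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
  perm <- sample(60)
  xt <- matrix(runif(10 * 18, 0, 60), 10)
  for (kind in c("multinomial_regression", "gradient_boosted_trees")) {
    p1 <- predict(train_classifier(kind, x, y, seed = 2), xt)
    p2 <- predict(train_classifier(kind, x[perm, ], y[perm], seed = 2), xt)
    expect_equal(p1, p2, tolerance = 1e-6)
  }
})

test_that("the network trains deterministically under a fixed seed", {
  set.seed(54)
  x <- rbind(matrix(rnorm(30 * 18, 10, 4), 30), matrix(rnorm(30 * 18, 30, 4), 30))
  y <- factor(rep(c("a", "b"), each = 30))
  xt <- matrix(rnorm(8 * 18, 20, 8), 8)
  p1 <- predict(train_classifier("feedforward_network", x, y, seed = 9), xt)
  p2 <- predict(train_classifier("feedforward_network", x, y, seed = 9), xt)
  expect_identical(p1, p2)
})

test_that("majority voting follows the agreement and tie-break rules", {
  preds <- list(
    multinomial_regression = c("A", "A", "A", "B"),
    gradient_boosted_trees = c("A", "B", "B", "C"),
    feedforward_network = c("B", "A", "C", "A")
  )
  out <- ensemble_predict(preds, best_kind = "gradient_boosted_trees")
  # (A,A,B) -> A; (A,B,A) -> A; (A,B,C) -> best; (B,C,A) -> best
  expect_equal(out, c("A", "A", "B", "C"))

  # unanimity: the ensemble equals each classifier
  u <- list(a = c("x", "y"), b = c("x", "y"), c = c("x", "y"))
  expect_equal(ensemble_predict(u, best_kind = "a"), c("x", "y"))
})

test_that("classification evaluation scores accuracy and AUC correctly", {
  truth <- c("a", "a", "b", "b")
  prob <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8), c(0.4, 0.6))
  colnames(prob) <- c("a", "b")
  ev <- evaluate_classification(c("a", "a", "b", "b"), truth, prob)
  expect_equal(ev$accuracy, 100)
  expect_equal(unname(ev$auc_per_class), c(1, 1))
  expect_equal(ev$auc_micro, 1)
  expect_equal(ev$auc_macro, 1)
  expect_error(evaluate_classification(character(0), character(0), prob),
               "empty test")
})

test_that("tree importances are normalized over the 18 hour features", {
  set.seed(55)
  x <- matrix(runif(120 * 18, 0, 60), 120)
  colnames(x) <- paste0("h", 6:23)
  # class depends only on two specific hours
  y <- factor(ifelse(x[, "h9"] + x[, "h15"] > 60, "hi", "lo"))
  fit <- train_classifier("gradient_boosted_trees", x, y, seed = 1)
  imp <- report_importance(fit)
  expect_length(imp, 18)
  expect_equal(sum(imp), 1, tolerance = 1e-8)
  expect_setequal(names(sort(imp, decreasing = TRUE))[1:2], c("h9", "h15"))
})

test_that("the full validation wrapper reports a coherent ensemble", {
  set.seed(56)
  centers <- list(c(50, 10, 5), c(10, 50, 5), c(5, 10, 50), c(25, 25, 25))
  x <- do.call(rbind, lapply(centers, function(cc) {
    cbind(matrix(rnorm(40 * 6, cc[1], 6), 40),
          matrix(rnorm(40 * 6, cc[2], 6), 40),
          matrix(rnorm(40 * 6, cc[3], 6), 40))
  }))
  x <- pmin(pmax(x, 0), 60)
  labels <- rep(c(1L, 2L, 3L, -1L), each = 40)
  D <- tibble::as_tibble(as.data.frame(x))
  names(D) <- paste0("h", 6:23)
  D <- dplyr::bind_cols(tibble::tibble(user_id = sprintf("u%03d", 1:160)), D)
  rep_out <- validate_clusters(D, labels, seed = 7)
  expect_equal(nrow(rep_out$classifiers), 3)
  expect_true(all(rep_out$classifiers$accuracy >= 0 &
                    rep_out$classifiers$accuracy <= 100))
  expect_true(all(c(rep_out$ensemble$auc_micro, rep_out$ensemble$auc_macro) <= 1))
  expect_equal(sum(rep_out$importance), 1, tolerance = 1e-8)
  # separable classes: the ensemble does well and beats the worst individual
  expect_gt(rep_out$ensemble$accuracy, 80)
  expect_gte(rep_out$ensemble$accuracy, min(rep_out$classifiers$accuracy))
})
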