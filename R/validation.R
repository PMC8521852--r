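#' Build the average-day matrix
#'
#' One row per user: the mean minutes of use in each clock hour across the
#' user's retained days. This is the classifier input for validating the
#' user segmentation.
#'
#' @param days Clean day table (`user_id`, `date`, `h6`..`h23`).
#' @param keep Optional logical keep-mask over rows of `days`.
#' @return Tibble `user_id`, `h6`..`h23`, sorted by `user_id`.
#' @export
build_average_day <- function(days, keep = NULL) {
  if (!is.null(keep)) {
    stopifnot(length(keep) == nrow(days))
    days <- days[keep, , drop = FALSE]
  }
  days |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(hour_cols()), mean),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$user_id)
}

#' Stratified train/test split
#'
#' Splits users into train and test sets, stratified by class so each
#' class's frequency is preserved to within rounding. Deterministic given
#' `seed`; the two index sets are disjoint and exhaustive.
#'
#' @param labels Class label per user.
#' @param train_frac Fraction assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_train_test <- function(labels, train_frac = 0.8, seed = 1L) {
  classes <- unique(labels)
  if (any(table(labels) < 5)) {
    abort("each class needs at least 5 users to split")
  }
  set.seed(seed)
  test <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_test <- max(1L, round(length(idx) * (1 - train_frac)))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

#' Train one classifier of the validation ensemble
#'
#' Three families are supported, configured as is conventional for this
#' validation task:
#'
#' * `"multinomial_regression"`: multinomial logistic regression with an L2
#'   (weight-decay) penalty, fitted by quasi-Newton (BFGS) optimization to
#'   convergence; inputs standardized on the training set.
#' * `"gradient_boosted_trees"`: 100 boosted trees, maximum depth 5,
#'   minimum split loss (gamma) 0, L1 weight regularization (alpha) 0.1;
#'   raw features.
#' * `"feedforward_network"`: fully connected 18-128-64-32-(classes)
#'   network, ReLU activations, cross-entropy loss, Adam optimizer, 25
#'   epochs; inputs standardized on the training set.
#'
#' @param kind Classifier family.
#' @param x Training feature matrix (users x 18 hours).
#' @param y Factor of class labels.
#' @param seed Integer seed (network initialization/shuffling, tree RNG).
#' @return A `wearday_classifier`; use [predict()] for class probabilities.
#' @export
train_classifier <- function(kind = c("multinomial_regression",
                                      "gradient_boosted_trees",
                                      "feedforward_network"),
                             x, y, seed = 1L) {
  kind <- match.arg(kind)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) abort("training data has a single class")
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  scaler <- NULL
  fit <- switch(kind,
    multinomial_regression = {
      scaler <- list(mu = colMeans(x), sd = pmax(apply(x, 2, sd), 1e-8))
      xs <- scale(x, scaler$mu, scaler$sd)
      df <- data.frame(.y = y, xs)
      nnet::multinom(.y ~ ., data = df, decay = 0.01, maxit = 500,
                     trace = FALSE)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
      xgboost::xgb.train(
        params = list(
          objective = "multi:softprob", num_class = nlevels(y),
          max_depth = 5, gamma = 0, alpha = 0.1, nthread = 1,
          seed = seed
        ),
        data = dtrain, nrounds = 100, verbose = 0
      )
    },
    feedforward_network = {
      scaler <- list(mu = colMeans(x), sd = pmax(apply(x, 2, sd), 1e-8))
      xs <- scale(x, scaler$mu, scaler$sd)
      mlp_train(xs, y, seed = seed)
    }
  )
  structure(
    list(kind = kind, fit = fit, scaler = scaler, levels = levels(y),
         features = colnames(x)),
    class = "wearday_classifier"
  )
}

#' @export
predict.wearday_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  colnames(x) <- object$features
  if (!is.null(object$scaler)) {
    x <- scale(x, object$scaler$mu, object$scaler$sd)
  }
  p <- switch(object$kind,
    multinomial_regression = {
      pr <- predict(object$fit, newdata = as.data.frame(x), type = "probs")
      if (is.null(dim(pr))) {           # two-class multinom returns a vector
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- object$levels
      }
      pr
    },
    gradient_boosted_trees = {
      pr <- predict(object$fit, xgboost::xgb.DMatrix(x))
      if (!is.matrix(pr)) {
        pr <- matrix(pr, ncol = length(object$levels), byrow = TRUE)
      }
      colnames(pr) <- object$levels
      pr
    },
    feedforward_network = mlp_predict(object$fit, x)
  )
  p[, object$levels, drop = FALSE]
}

#' Majority-vote ensemble prediction
#'
#' Each user gets the label at least two of the three classifiers agree
#' on; when all three disagree, the best performing individual classifier
#' decides.
#'
#' @param predictions List of three aligned label vectors, named by
#'   classifier kind.
#' @param best_kind Name of the designated best classifier.
#' @return Label vector.
#' @export
ensemble_predict <- function(predictions, best_kind) {
  stopifnot(length(predictions) == 3, best_kind %in% names(predictions))
  pm <- do.call(cbind, lapply(predictions, as.character))
  apply_row <- function(i) {
    tab <- table(pm[i, ])
    if (max(tab) >= 2) names(tab)[which.max(tab)] else pm[i, best_kind]
  }
  vapply(seq_len(nrow(pm)), apply_row, character(1))
}

#' Accuracy and ROC-AUC of a set of predictions
#'
#' Accuracy is the percentage of correct test predictions. AUCs are
#' one-vs-rest: each class is binarized and scored with its probability
#' column; the micro-average pools all binarized decisions, the macro is
#' the unweighted mean of per-class AUCs.
#'
#' @param pred Predicted label vector.
#' @param truth True label vector.
#' @param scores Class-probability matrix (columns named by class).
#' @return List `accuracy` (percent), `auc_micro`, `auc_macro`,
#'   `auc_per_class`.
#' @export
evaluate_classification <- function(pred, truth, scores) {
  if (length(truth) == 0) abort("empty test set")
  auc <- multiclass_auc(scores, as.character(truth))
  list(
    accuracy = 100 * mean(as.character(pred) == as.character(truth)),
    auc_micro = auc$micro,
    auc_macro = auc$macro,
    auc_per_class = auc$per_class
  )
}

#' Hour-level feature importances from the boosted-trees model
#'
#' Gain-based importances over the 18 hour features, normalized to sum
#' to 1. Hours never used in a split get importance 0.
#'
#' @param model A `wearday_classifier` of kind `"gradient_boosted_trees"`.
#' @return Named numeric vector over `h6`..`h23`.
#' @export
report_importance <- function(model) {
  stopifnot(model$kind == "gradient_boosted_trees")
  imp <- xgboost::xgb.importance(model = model$fit)
  out <- setNames(rep(0, length(model$features)), model$features)
  out[imp$Feature] <- imp$Gain
  out / sum(out)
}

#' Validate a user clustering with a classifier ensemble
#'
#' Trains the three classifiers on an 80/20 stratified split of the
#' average-day matrix against the cluster labels (noise included as its
#' own class), combines them by majority vote with best-classifier
#' tie-break, and reports accuracy and micro/macro ROC-AUC for each
#' classifier and the ensemble, plus the boosted-trees feature
#' importances. Ensemble probability scores are the unweighted mean of the
#' three classifiers' probabilities.
#'
#' @param D Average-day tibble from [build_average_day()] (or matrix).
#' @param labels Cluster label per user (aligned with rows of `D`); `-1`
#'   is reported as class `"noise"`.
#' @param train_frac Training fraction.
#' @param seed Integer seed for the split and classifier training.
#' @return An `ensemble_report`: `classifiers` tibble (kind, accuracy,
#'   micro/macro AUC), `ensemble` row, `auc_per_class`, `importance`,
#'   `best_kind`, `split`.
#' @export
validate_clusters <- function(D, labels, train_frac = 0.8, seed = 7L) {
  x <- if (is.data.frame(D)) as.matrix(D[hour_cols()]) else as.matrix(D)
  colnames(x) <- hour_cols()
  cls <- ifelse(labels == -1, "noise", paste0("G", labels))
  y <- factor(cls)
  split <- split_train_test(cls, train_frac = train_frac, seed = seed)
  kinds <- c("multinomial_regression", "gradient_boosted_trees",
             "feedforward_network")
  models <- lapply(kinds, function(kind) {
    train_classifier(kind, x[split$train, , drop = FALSE], y[split$train],
                     seed = derive_seed(seed, match(kind, kinds)))
  })
  names(models) <- kinds
  probs <- lapply(models, function(mod) predict(mod, x[split$test, , drop = FALSE]))
  preds <- lapply(probs, function(p) colnames(p)[max.col(p, ties.method = "first")])
  truth <- as.character(y[split$test])
  indiv <- purrr::map_dfr(kinds, function(kind) {
    ev <- evaluate_classification(preds[[kind]], truth, probs[[kind]])
    tibble::tibble(
      classifier = kind, accuracy = ev$accuracy,
      auc_micro = ev$auc_micro, auc_macro = ev$auc_macro
    )
  })
  best_kind <- indiv$classifier[which.max(indiv$accuracy)]
  ens_pred <- ensemble_predict(preds, best_kind)
  ens_scores <- Reduce(`+`, probs) / length(probs)
  ens_eval <- evaluate_classification(ens_pred, truth, ens_scores)
  structure(
    list(
      classifiers = indiv,
      ensemble = tibble::tibble(
        classifier = "ensemble", accuracy = ens_eval$accuracy,
        auc_micro = ens_eval$auc_micro, auc_macro = ens_eval$auc_macro
      ),
      auc_per_class = ens_eval$auc_per_class,
      importance = report_importance(models$gradient_boosted_trees),
      best_kind = best_kind,
      split = split,
      models = models
    ),
    class = "ensemble_report"
  )
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat("<ensemble_report> best individual classifier: ", x$best_kind, "\n",
      sep = "")
  print(tidy(x))
  top <- names(sort(x$importance, decreasing = TRUE))[1:2]
  cat("  top boosted-tree features:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy ensemble_report
#' @export
tidy.ensemble_report <- function(x, ...) {
  dplyr::bind_rows(x$classifiers, x$ensemble)
}

#' @method glance ensemble_report
#' @export
glance.ensemble_report <- function(x, ...) {
  tibble::tibble(
    ensemble_accuracy = x$ensemble$accuracy,
    ensemble_auc_micro = x$ensemble$auc_micro,
    ensemble_auc_macro = x$ensemble$auc_macro,
    best_kind = x$best_kind
  )
}

#' Feature-importance bar plot
#'
#' @param object An `ensemble_report`.
#' @param ... Unused.
#' @return A ggplot of gain importance by clock hour.
#' @method autoplot ensemble_report
#' @export
autoplot.ensemble_report <- function(object, ...) {
  tibble::tibble(
    hour = as.integer(sub("^h", "", names(object$importance))),
    importance = unname(object$importance)
  ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$hour, y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "clock hour", y = "gain importance") +
    ggplot2::theme_minimal()
}
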