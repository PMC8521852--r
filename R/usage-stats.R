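#' Hours of hearing aid use in a day
#'
#' Sums the 18 hourly minutes-of-use values and converts to hours. Given a
#' day table, appends an `hours` column; given a bare numeric vector,
#' returns the scalar total.
#'
#' @param x A day table with `h6`..`h23` columns, or a numeric vector of 18
#'   hourly minutes.
#' @return The input tibble with an `hours` column, or a scalar in
#'   \[0, 18\].
#' @export
daily_hours <- function(x) {
  if (is.data.frame(x)) {
    x$hours <- rowSums(day_matrix(x)) / 60
    return(x)
  }
  sum(x) / 60
}

#' Cohort amount-of-use summary
#'
#' Computes the descriptives of daily wear time: pooled day-level mean and
#' SD; per-user mean hours and within-user SD (sample SD across the user's
#' days); the first and third quartiles of the per-user means (linear
#' interpolation convention); light/medium/heavy user segments (below Q1 /
#' between the quartiles / above Q3); and the coefficient of variation of
#' the per-user means.
#'
#' @param days Clean day table (`user_id`, `date`, `h6`..`h23`).
#' @return A `use_summary` object: list with `pooled` (day-level mean/sd/n),
#'   `users` (per-user tibble with `segment`), `quartiles`, `cv`, and
#'   `segment_means`.
#' @export
cohort_use_summary <- function(days) {
  days <- daily_hours(days)
  if (dplyr::n_distinct(days$user_id) < 2) {
    abort("cohort_use_summary() needs at least 2 users")
  }
  users <- days |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_hours = mean(.data$hours),
      within_sd = sd(.data$hours),
      .groups = "drop"
    )
  q <- quantile(users$mean_hours, c(0.25, 0.75), type = 7, names = FALSE)
  users$segment <- dplyr::case_when(
    users$mean_hours < q[1] ~ "light",
    users$mean_hours > q[2] ~ "heavy",
    TRUE ~ "medium"
  )
  structure(
    list(
      pooled = tibble::tibble(
        n_days = nrow(days),
        mean_hours = mean(days$hours),
        sd_hours = sd(days$hours)
      ),
      users = users,
      quartiles = setNames(q, c("q1", "q3")),
      cv = sd(users$mean_hours) / mean(users$mean_hours),
      segment_means = users |>
        dplyr::group_by(.data$segment) |>
        dplyr::summarise(
          n = dplyr::n(),
          mean_hours = mean(.data$mean_hours),
          mean_within_sd = mean(.data$within_sd, na.rm = TRUE),
          .groups = "drop"
        )
    ),
    class = "use_summary"
  )
}

#' @export
print.use_summary <- function(x, ...) {
  cat("<use_summary> ", nrow(x$users), " users, ", x$pooled$n_days, " days\n",
      sep = "")
  cat(sprintf(
    "  per-user mean use %.2f h (SD %.2f, CV %.3f); Q1 %.2f, Q3 %.2f\n",
    mean(x$users$mean_hours), sd(x$users$mean_hours), x$cv,
    x$quartiles[1], x$quartiles[2]
  ))
  print(x$segment_means)
  invisible(x)
}

#' @method tidy use_summary
#' @export
tidy.use_summary <- function(x, ...) x$users

#' @method glance use_summary
#' @export
glance.use_summary <- function(x, ...) {
  tibble::tibble(
    n_users = nrow(x$users),
    n_days = x$pooled$n_days,
    pooled_mean_hours = x$pooled$mean_hours,
    pooled_sd_hours = x$pooled$sd_hours,
    user_mean_hours = mean(x$users$mean_hours),
    user_sd_hours = sd(x$users$mean_hours),
    cv = x$cv,
    q1 = x$quartiles[[1]],
    q3 = x$quartiles[[2]]
  )
}

#' Contrast within-user variability between two user segments
#'
#' Classical two-sample pooled-variance t-test with Cohen's d (pooled-SD
#' denominator), as used to compare the day-to-day variability of medium
#' users against light and heavy users.
#'
#' @param x,y Numeric vectors (e.g. within-user SDs of two segments).
#' @param var_equal Use the pooled-variance test (default); `FALSE` gives
#'   Welch.
#' @return One-row tibble: `t_stat`, `df`, `p_value`, `cohens_d`.
#' @export
segment_contrast <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2 || length(y) < 2) abort("both segments need >= 2 values")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
  tibble::tibble(
    t_stat = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    cohens_d = d
  )
}

#' Fit the quadratic variability curve
#'
#' Models within-user SD (y, hours) as a function of mean daily use
#' (x, hours) with a second-order polynomial through the origin,
#' `y = b1 x + b2 x^2`. With `b2 < 0` the curve peaks at `-b1 / (2 b2)`:
#' day-to-day variability rises with use up to the peak and falls beyond
#' it. R-squared is computed against the zero baseline, consistent with
#' no-intercept least squares.
#'
#' @param users Per-user tibble with `mean_hours` and `within_sd` (as from
#'   [cohort_use_summary()]).
#' @return A `variability_fit`: `b1`, `b2`, `r_squared`, `peak_hours`, and
#'   the underlying `lm` fit.
#' @export
fit_variability_curve <- function(users) {
  users <- users[!is.na(users$within_sd), , drop = FALSE]
  if (nrow(users) < 3) abort("need at least 3 users to fit the curve")
  fit <- lm(within_sd ~ 0 + mean_hours + I(mean_hours^2), data = users)
  b <- unname(coef(fit))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
  structure(
    list(
      b1 = b[1], b2 = b[2], r_squared = r2,
      peak_hours = if (!is.na(b[2]) && b[2] < 0) -b[1] / (2 * b[2]) else NA_real_,
      fit = fit
    ),
    class = "variability_fit"
  )
}

#' @export
print.variability_fit <- function(x, ...) {
  cat(sprintf(
    "<variability_fit> y = %.3f x %+.4f x^2 (R^2 = %.3f)\n", x$b1, x$b2,
    x$r_squared
  ))
  if (!is.na(x$peak_hours)) {
    cat(sprintf("  variability peaks around %.1f h/day\n", x$peak_hours))
  }
  invisible(x)
}

#' @method tidy variability_fit
#' @export
tidy.variability_fit <- function(x, ...) {
  tibble::tibble(term = c("x", "x^2"), estimate = c(x$b1, x$b2))
}

#' @method glance variability_fit
#' @export
glance.variability_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, peak_hours = x$peak_hours)
}

#' Scatter of per-user mean use vs within-user variability
#'
#' @param object A `use_summary`.
#' @param curve Optional `variability_fit` overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot use_summary
#' @export
autoplot.use_summary <- function(object, curve = NULL, ...) {
  p <- ggplot2::ggplot(
    object$users,
    ggplot2::aes(x = .data$mean_hours, y = .data$within_sd,
                 colour = .data$segment)
  ) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "mean use (h/day)", y = "within-user SD (h)", colour = "segment"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(curve)) {
    xs <- seq(0, 18, length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(
        mean_hours = xs, within_sd = curve$b1 * xs + curve$b2 * xs^2,
        segment = NA_character_
      ),
      colour = "black"
    )
  }
  p
}
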