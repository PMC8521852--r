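# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# A small default cohort with its preprocessed day table.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    co <- generate_cohort(cohort_config(n_users = 60, seed = 5))
    prep <- preprocess_logs(co$logs, co$windows)
    .fixtures$small <- list(cohort = co, prep = prep,
                            days = build_day_matrix(prep$days))
  }
  .fixtures$small
}

# A wide day row from a plain numeric vector of 18 hourly minutes.
day_row <- function(user, date, minutes) {
  stopifnot(length(minutes) == 18)
  out <- tibble::tibble(user_id = user, date = as.Date(date))
  out[paste0("h", 6:23)] <- as.list(as.numeric(minutes))
  out
}

day_rows <- function(...) dplyr::bind_rows(...)

# Long two-ear logs for one user-day from left/right hourly vectors.
logs_for_day <- function(user, date, left, right = left) {
  tibble::tibble(
    user_id = user, date = as.Date(date), hour = rep(6:23, 2),
    side = rep(c("L", "R"), each = 18),
    minutes = c(left, right), connected = 1L
  )
}

# Constant-use day vector with the given total hours of use.
flat_day <- function(hours_total) rep(hours_total * 60 / 18, 18)

empty_windows_tbl <- function() {
  tibble::tibble(
    user_id = character(), date = as.Date(character()),
    start_hour = integer(), end_hour = integer(), counter_minutes = numeric()
  )
}

proportion_matrix_test <- function(B) {
  as.matrix(B[grep("^p_", names(B))])
}
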