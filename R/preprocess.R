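#' Resolve left and right ear logs into a single hourly series
#'
#' For binaural users the two ears can log different amounts in the same
#' hour; the larger value is taken, hour by hour. An hour present on only
#' one side keeps that side's value. Hours masked on both sides (missing
#' minutes, e.g. inside a disconnection window) stay missing for the
#' imputation step.
#'
#' @param logs Long log tibble (`user_id`, `date`, `hour`, `side`,
#'   `minutes`, `connected`).
#' @return Tibble `user_id`, `date`, `hour`, `minutes`, `connected` with one
#'   row per (user, date, hour).
#' @export
resolve_binaural <- function(logs) {
  wide <- tidyr::pivot_wider(
    logs,
    id_cols = c("user_id", "date", "hour"),
    names_from = "side", values_from = c("minutes", "connected")
  )
  mcols <- grep("^minutes_", names(wide), value = TRUE)
  ccols <- grep("^connected_", names(wide), value = TRUE)
  mm <- as.matrix(wide[mcols])
  minutes <- do.call(pmax, c(lapply(seq_along(mcols), function(j) mm[, j]),
                             list(na.rm = TRUE)))
  minutes[is.nan(minutes) | is.infinite(minutes)] <- NA_real_
  cm <- as.matrix(wide[ccols])
  connected <- do.call(pmax, c(lapply(seq_along(ccols), function(j) cm[, j]),
                               list(na.rm = TRUE)))
  connected[is.infinite(connected)] <- 0L
  tibble::tibble(
    user_id = wide$user_id, date = wide$date, hour = wide$hour,
    minutes = as.numeric(minutes), connected = as.integer(connected)
  )
}

#' Impute hourly use over a temporary disconnection window
#'
#' While disconnected the device cannot stream hourly estimates, but an
#' embedded time counter still accumulates total minutes of use. If the
#' counter shows full-time use (60 min for every disconnected hour) that
#' use is assigned directly to the hours of disconnection; otherwise the
#' counted minutes are distributed evenly among them (e.g. 60 min over a
#' 2-h disconnection becomes 30 min/h). Totals are conserved exactly and
#' fractional minutes are kept.
#'
#' @param start_hour,end_hour Inclusive clock-hour bounds of the window,
#'   within 6..23.
#' @param counter_minutes Total minutes of use recorded by the counter;
#'   at most 60 per disconnected hour.
#' @return List with `minutes` (one value per window hour) and `flag`
#'   (`"full_time"` or `"on_off"`).
#' @export
impute_disconnection <- function(start_hour, end_hour, counter_minutes) {
  if (start_hour < 6 || end_hour > 23 || start_hour > end_hour) {
    abort("window must satisfy 6 <= start_hour <= end_hour <= 23")
  }
  n_hours <- end_hour - start_hour + 1
  if (counter_minutes < 0 || counter_minutes > 60 * n_hours) {
    abort(sprintf(
      "counter_minutes (%g) outside [0, %d] for a %d-hour window",
      counter_minutes, 60L * n_hours, n_hours
    ))
  }
  if (counter_minutes == 60 * n_hours) {
    list(minutes = rep(60, n_hours), flag = "full_time")
  } else {
    list(minutes = rep(counter_minutes / n_hours, n_hours), flag = "on_off")
  }
}

window_flags <- function(windows) {
  if (nrow(windows) == 0) {
    return(tibble::tibble(
      user_id = character(), date = as.Date(character()),
      long_onoff = logical()
    ))
  }
  windows |>
    dplyr::mutate(
      n_hours = .data$end_hour - .data$start_hour + 1,
      on_off = .data$counter_minutes < 60 * .data$n_hours
    ) |>
    dplyr::group_by(.data$user_id, .data$date) |>
    dplyr::summarise(
      long_onoff = any(.data$on_off & .data$n_hours > 2),
      .groups = "drop"
    )
}

expand_windows <- function(windows) {
  windows |>
    dplyr::rowwise() |>
    dplyr::mutate(
      hour = list(seq(.data$start_hour, .data$end_hour)),
      imputed = list(impute_disconnection(
        .data$start_hour, .data$end_hour, .data$counter_minutes
      )$minutes)
    ) |>
    dplyr::ungroup() |>
    tidyr::unnest(c("hour", "imputed")) |>
    dplyr::select("user_id", "date", "hour", "imputed")
}

#' Filter days and users to the clean analysis set
#'
#' Applies the five inclusion criteria, in order: (1) drop days containing
#' an on-off disconnection window longer than 2 h (the even-spread
#' imputation would flatten too much of such a day); (2) drop days with any
#' hour above 60 min (malformed input); (3) drop days with less than 60 min
#' of total use; (4) restrict to clock hours 6:00-23:59 (applied when the
#' day vectors are built; counted here for the audit); (5) drop users with
#' fewer than 10 retained days, together with all their days.
#'
#' @param days Wide day table (`user_id`, `date`, `h6`..`h23`).
#' @param windows Disconnection windows with counters (used for rule 1).
#' @param hours_dropped Number of out-of-window log records discarded at
#'   construction, recorded under rule 4.
#' @return List with `days` (retained rows, sorted) and `audit`
#'   (a `wearday_audit`: per-rule removal counts plus totals).
#' @export
clean_days <- function(days, windows = empty_windows(), hours_dropped = 0) {
  n_input <- nrow(days)
  flags <- window_flags(windows)
  days <- dplyr::left_join(days, flags, by = c("user_id", "date"))
  days$long_onoff[is.na(days$long_onoff)] <- FALSE

  r1 <- days$long_onoff
  days <- days[!r1, , drop = FALSE]

  m <- day_matrix(days)
  r2 <- rowSums(m > 60) > 0
  days <- days[!r2, , drop = FALSE]

  m <- day_matrix(days)
  r3 <- rowSums(m) < 60
  days <- days[!r3, , drop = FALSE]

  n_days_user <- table(days$user_id)
  dropped_users <- names(n_days_user)[n_days_user < 10]
  r5 <- days$user_id %in% dropped_users
  days <- days[!r5, , drop = FALSE]

  days <- days |>
    dplyr::select(-"long_onoff") |>
    dplyr::arrange(.data$user_id, .data$date)

  audit <- structure(
    list(
      rules = tibble::tibble(
        rule = c(
          "long_on_off_disconnection", "hour_over_60_min",
          "total_under_60_min", "hours_outside_6_to_24", "user_under_10_days"
        ),
        days_removed = c(sum(r1), sum(r2), sum(r3), 0L, sum(r5)),
        note = c("", "", "",
                 sprintf("%d hourly records discarded at construction", hours_dropped),
                 sprintf("%d users dropped", length(dropped_users)))
      ),
      n_input = n_input,
      n_retained = nrow(days),
      users_dropped = dropped_users,
      hours_dropped = hours_dropped
    ),
    class = "wearday_audit"
  )
  stopifnot(audit$n_retained + sum(audit$rules$days_removed) == n_input)
  list(days = days, audit = audit)
}

#' @export
print.wearday_audit <- function(x, ...) {
  cat("<wearday_audit> ", x$n_input, " days in, ", x$n_retained, " retained\n",
      sep = "")
  print(x$rules)
  invisible(x)
}

#' Build the clean day-by-hour matrix from raw logs
#'
#' Runs the full preprocessing chain: binaural resolution (per-hour max of
#' the two ears), disconnection imputation from window counters, hour-window
#' restriction, and the five-rule day/user filter. The result is the
#' analysis substrate: one row per retained day with 18 hourly
#' minutes-of-use columns.
#'
#' @param logs Long log tibble (`user_id`, `date`, `hour`, `side`,
#'   `minutes`, `connected`).
#' @param windows Disconnection windows (`user_id`, `date`, `start_hour`,
#'   `end_hour`, `counter_minutes`).
#' @return List with `days` (tibble `user_id`, `date`, `h6`..`h23`, sorted
#'   by user then date) and `audit` (see [clean_days()]).
#' @export
preprocess_logs <- function(logs, windows = empty_windows()) {
  if (nrow(logs) == 0) {
    abort("empty input: no log records to preprocess")
  }
  in_window <- logs$hour >= 6 & logs$hour <= 23
  hours_dropped <- sum(!in_window)
  logs <- logs[in_window, , drop = FALSE]

  resolved <- resolve_binaural(logs)

  if (nrow(windows) > 0) {
    wexp <- expand_windows(windows)
    key_r <- paste(resolved$user_id, resolved$date, resolved$hour)
    key_w <- paste(wexp$user_id, wexp$date, wexp$hour)
    hit <- match(key_r, key_w)
    resolved$minutes[!is.na(hit)] <- wexp$imputed[hit[!is.na(hit)]]
  }
  # masked hours not covered by any counter window: treat as no use
  resolved$minutes[is.na(resolved$minutes)] <- 0

  days <- resolved |>
    dplyr::mutate(hour = paste0("h", .data$hour)) |>
    tidyr::pivot_wider(
      id_cols = c("user_id", "date"),
      names_from = "hour", values_from = "minutes", values_fill = 0
    )
  for (h in setdiff(hour_cols(), names(days))) days[[h]] <- 0
  days <- days[c("user_id", "date", hour_cols())]

  clean_days(days, windows, hours_dropped = hours_dropped)
}

#' Order retained days into the day-by-hour analysis table
#'
#' @param days Retained day rows from [clean_days()].
#' @return The same tibble sorted by `user_id` then `date`, columns
#'   `user_id`, `date`, `h6`..`h23`.
#' @export
build_day_matrix <- function(days) {
  days |>
    dplyr::arrange(.data$user_id, .data$date) |>
    dplyr::select("user_id", "date", dplyr::all_of(hour_cols()))
}
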