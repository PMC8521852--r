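#' Archetypal day-of-use templates
#'
#' The generator draws each logged day from one of three archetypal hourly
#' wear-time patterns, plus an "atypical" catch-all:
#'
#' * `full_day`: the aids go on in the morning (around 7:00) and come off in
#'   the evening (around 22:00), with near-continuous use in between.
#' * `afternoon`: use starts in the late morning (around 11:00) and runs
#'   uninterrupted until the evening.
#' * `sporadic_evening`: a short bout of use (< 4 h in expectation)
#'   concentrated after 17:00.
#' * `atypical`: no structured pattern; each hour is drawn uniformly on
#'   \[0, 60\] minutes.
#'
#' `mean_curve` holds the expected minutes of use for clock hours 6..23.
#' `onset_jitter_sd` and `duration_jitter_sd` (hours) control day-to-day
#' shifts of the active window; `hourly_noise_sd` (minutes) is additive noise
#' on active hours. All draws are clamped to \[0, 60\].
#'
#' @return A tibble with one row per archetype: `name`, `mean_curve`
#'   (list-column of 18 values), `onset_jitter_sd`, `duration_jitter_sd`,
#'   `hourly_noise_sd`.
#' @export
archetype_templates <- function() {
  full_day <- c(30, rep(55, 15), 30, 0)           # h6, h7..h21, h22, h23
  afternoon <- c(rep(0, 5), rep(50, 11), 30, 0)   # h6..h10, h11..h21, h22, h23
  sporadic <- c(rep(0, 12), rep(47, 4), 25, 0)    # h6..h17, h18..h21, h22, h23
  tibble::tibble(
    name = c("full_day", "afternoon", "sporadic_evening", "atypical"),
    mean_curve = list(full_day, afternoon, sporadic, rep(NA_real_, 18)),
    onset_jitter_sd = c(0.5, 0.5, 0.25, 0),
    duration_jitter_sd = c(0.5, 0.5, 0.25, 0),
    hourly_noise_sd = c(25, 25, 10, 0)
  )
}

day_type_levels <- function() c("full_day", "afternoon", "sporadic_evening", "atypical")
archetype_levels <- function() c("full_day", "afternoon", "sporadic_evening")

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the logging study the package is built around: user
#' groups A/B/C/noise in shares 49/15/20/15 percent, each non-noise group
#' spending on average 60 percent of days in its predominant day type
#' (Dirichlet mixing, concentration 20), about 28 logged days per user
#' (SD 18) over a four-month window, 3 percent atypical days, and occasional
#' Bluetooth disconnection windows carrying on-device minute counters.
#'
#' @param n_users Number of users to simulate.
#' @param days_per_user Length-2 numeric `(mean, sd)` of logged days per user.
#' @param group_weights Probabilities of groups `A`, `B`, `C`, `noise`;
#'   must sum to 1.
#' @param dominant_proportion Expected share of a non-noise user's days spent
#'   in the group's predominant day type; must lie in (1/3, 1\].
#' @param mixture_concentration Dirichlet concentration of per-user mixtures.
#' @param day_type_weights_global Optional length-4 override of the marginal
#'   day-type shares (`full_day`, `afternoon`, `sporadic_evening`,
#'   `atypical`); when set, day types are drawn i.i.d. from these weights
#'   instead of per-user mixtures.
#' @param atypical_day_rate Probability that a day is atypical (ignored when
#'   `day_type_weights_global` is set).
#' @param disconnect_rate Probability that a logged day contains one
#'   temporary disconnection window.
#' @param disconnect_full_use_prob Probability that a disconnection covers
#'   full-time use (60 min in every disconnected hour).
#' @param weekend_multiplier Multiplier applied to the afternoon and sporadic
#'   mixture components on Saturdays/Sundays; 1 disables the weekday effect.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_users = 500,
                          days_per_user = c(28, 18),
                          group_weights = c(A = 7862, B = 2442, C = 3148,
                                            noise = 2453) / 15905,
                          dominant_proportion = 0.60,
                          mixture_concentration = 20,
                          day_type_weights_global = NULL,
                          atypical_day_rate = 0.03,
                          disconnect_rate = 0.10,
                          disconnect_full_use_prob = 0.30,
                          weekend_multiplier = 1,
                          seed = 1L) {
  stopifnot(length(days_per_user) == 2, length(group_weights) == 4)
  if (n_users < 0) abort("`n_users` must be non-negative")
  if (abs(sum(group_weights) - 1) > 1e-8) abort("`group_weights` must sum to 1")
  if (dominant_proportion <= 1 / 3 || dominant_proportion > 1) {
    abort("`dominant_proportion` must lie in (1/3, 1]")
  }
  if (mixture_concentration <= 0) abort("`mixture_concentration` must be positive")
  if (!is.null(day_type_weights_global)) {
    stopifnot(length(day_type_weights_global) == 4)
    if (abs(sum(day_type_weights_global) - 1) > 1e-8) {
      abort("`day_type_weights_global` must sum to 1")
    }
  }
  structure(
    list(
      n_users = as.integer(n_users),
      days_per_user = as.numeric(days_per_user),
      group_weights = setNames(as.numeric(group_weights), c("A", "B", "C", "noise")),
      dominant_proportion = dominant_proportion,
      mixture_concentration = mixture_concentration,
      day_type_weights_global = day_type_weights_global,
      atypical_day_rate = atypical_day_rate,
      disconnect_rate = disconnect_rate,
      disconnect_full_use_prob = disconnect_full_use_prob,
      weekend_multiplier = weekend_multiplier,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a <= 0) 0 else rgamma(1, shape = a), numeric(1))
  if (sum(g) == 0) return(rep(1 / length(alpha), length(alpha)))
  g / sum(g)
}

group_mean_mixture <- function(group, dominant_proportion) {
  rest <- (1 - dominant_proportion) / 2
  switch(group,
    A = c(dominant_proportion, rest, rest),
    B = c(rest, dominant_proportion, rest),
    C = c(rest, rest, dominant_proportion),
    noise = rep(1 / 3, 3),
    abort(paste0("unknown group label: ", group))
  )
}

#' Draw a user's day-type mixture
#'
#' Non-noise groups draw from a Dirichlet whose mean puts
#' `dominant_proportion` on the group's predominant archetype (full day for
#' A, afternoon for B, sporadic evening for C); noise users draw from the
#' flat Dirichlet(1,1,1). Uses the current RNG state.
#'
#' @param group One of `"A"`, `"B"`, `"C"`, `"noise"`.
#' @param config A [cohort_config()].
#' @return A probability 3-vector over the archetypes, summing to 1.
#' @export
sample_user_mixture <- function(group, config = cohort_config()) {
  mu <- group_mean_mixture(group, config$dominant_proportion)
  alpha <- if (identical(group, "noise")) rep(1, 3) else mu * config$mixture_concentration
  p <- rdirichlet1(alpha)
  setNames(p, archetype_levels())
}

shift_curve <- function(v, s) {
  n <- length(v)
  out <- numeric(n)
  if (s >= 0) {
    out[(1 + s):n] <- v[1:(n - s)]
  } else {
    out[1:(n + s)] <- v[(1 - s):n]
  }
  out
}

adjust_duration <- function(v, d) {
  active <- which(v > 0)
  if (length(active) == 0 || d == 0) return(v)
  last <- max(active)
  if (d > 0) {
    idx <- seq(last + 1, min(last + d, length(v)))
    if (length(idx) > 0 && idx[1] <= length(v)) v[idx] <- v[last]
  } else {
    drop <- utils::tail(active, min(-d, length(active)))
    v[drop] <- 0
  }
  v
}

#' Draw one day's hourly wear-time vector from an archetype template
#'
#' Applies integer onset/duration jitter to the template's active window,
#' adds Gaussian noise to active hours, and clamps to \[0, 60\] minutes.
#' With all jitter and noise at zero the template mean curve is returned
#' exactly. Atypical days are uniform draws on \[0, 60\] for every hour.
#'
#' @param day_type Archetype name; must match `template$name`.
#' @param template A row of [archetype_templates()] (as a list or
#'   one-row tibble).
#' @return Numeric vector of 18 minutes-of-use values (hours 6..23).
#' @export
sample_day_vector <- function(day_type, template) {
  if (is.data.frame(template)) template <- as.list(template[1, ])
  if (is.list(template$mean_curve) && !is.numeric(template$mean_curve)) {
    template$mean_curve <- template$mean_curve[[1]]
  }
  if (!identical(day_type, template$name)) {
    abort("`template` does not match `day_type`")
  }
  if (identical(day_type, "atypical")) {
    return(runif(18, 0, 60))
  }
  v <- template$mean_curve
  s <- if (template$onset_jitter_sd > 0) round(rnorm(1, 0, template$onset_jitter_sd)) else 0
  d <- if (template$duration_jitter_sd > 0) round(rnorm(1, 0, template$duration_jitter_sd)) else 0
  s <- max(min(s, 17), -17)
  v <- shift_curve(v, s)
  v <- adjust_duration(v, d)
  if (template$hourly_noise_sd > 0) {
    active <- v > 0
    v[active] <- v[active] + rnorm(sum(active), 0, template$hourly_noise_sd)
  }
  pmin(pmax(v, 0), 60)
}

#' Inject temporary disconnection windows into an hourly log
#'
#' Emulates the device losing its smartphone connection: inside each window
#' the hourly log is masked (minutes set to missing, connection flag
#' cleared) while an on-device counter records the true minutes of use over
#' the whole window. With probability `disconnect_full_use_prob` the window
#' covers full-time use (the underlying minutes are set to 60 for every
#' disconnected hour before the counter is read).
#'
#' @param logs Long log tibble (`user_id`, `date`, `hour`, `side`,
#'   `minutes`, `connected`).
#' @param config A [cohort_config()]; `disconnect_rate` picks the affected
#'   days. Uses the current RNG state.
#' @param windows Optional pre-specified window tibble (`user_id`, `date`,
#'   `start_hour`, `end_hour`); when supplied it is validated (within hours
#'   6..23, non-overlapping per day) and used as-is.
#' @return A list with elements `logs` (masked log) and `windows`
#'   (`user_id`, `date`, `start_hour`, `end_hour`, `counter_minutes`).
#' @export
inject_disconnections <- function(logs, config = cohort_config(), windows = NULL) {
  internal_windows <- is.null(windows)
  if (internal_windows) {
    day_keys <- dplyr::distinct(logs, .data$user_id, .data$date)
    if (nrow(day_keys) == 0 || config$disconnect_rate <= 0) {
      return(list(logs = logs, windows = empty_windows()))
    }
    hit <- runif(nrow(day_keys)) < config$disconnect_rate
    day_keys <- day_keys[hit, , drop = FALSE]
    if (nrow(day_keys) == 0) {
      return(list(logs = logs, windows = empty_windows()))
    }
    len <- sample(1:3, nrow(day_keys), replace = TRUE)
    start <- vapply(len, function(l) sample(6:(23 - l + 1), 1), numeric(1))
    windows <- tibble::tibble(
      user_id = day_keys$user_id, date = day_keys$date,
      start_hour = as.integer(start), end_hour = as.integer(start + len - 1)
    )
  } else {
    windows <- tibble::as_tibble(windows)
    if (any(windows$start_hour < 6 | windows$end_hour > 23 |
              windows$start_hour > windows$end_hour)) {
      abort("disconnection windows must satisfy 6 <= start_hour <= end_hour <= 23")
    }
    overlaps <- windows |>
      dplyr::group_by(.data$user_id, .data$date) |>
      dplyr::arrange(.data$start_hour, .by_group = TRUE) |>
      dplyr::summarise(
        bad = dplyr::n() > 1 && any(.data$start_hour[-1] <= head(.data$end_hour, -1)),
        .groups = "drop"
      )
    if (any(overlaps$bad)) abort("overlapping disconnection windows on the same day")
  }
  if (nrow(windows) == 0) {
    return(list(logs = logs, windows = empty_windows()))
  }

  # expand windows to (user, date, hour) keys
  wexp <- windows |>
    dplyr::mutate(.win = dplyr::row_number()) |>
    dplyr::rowwise() |>
    dplyr::mutate(hour = list(seq(.data$start_hour, .data$end_hour))) |>
    dplyr::ungroup() |>
    tidyr::unnest("hour")

  full_use <- if (internal_windows) {
    runif(nrow(windows)) < config$disconnect_full_use_prob
  } else {
    rep(FALSE, nrow(windows))
  }
  key_log <- paste(logs$user_id, logs$date, logs$hour)
  key_win <- paste(wexp$user_id, wexp$date, wexp$hour)
  in_win <- match(key_log, key_win)
  masked <- !is.na(in_win)
  rows_masked <- which(masked)
  win_of_masked <- wexp$.win[in_win[masked]]

  # full-time use rewrites the underlying minutes to 60 before counters read
  logs$minutes[rows_masked[full_use[win_of_masked]]] <- 60

  # counters record the binaurally-resolved true minutes inside the window
  resolved <- logs[masked, ] |>
    dplyr::group_by(.data$user_id, .data$date, .data$hour) |>
    dplyr::summarise(minutes = max(.data$minutes), .groups = "drop")
  rkey <- paste(resolved$user_id, resolved$date, resolved$hour)
  resolved$.win <- wexp$.win[match(rkey, key_win)]
  counters <- resolved |>
    dplyr::group_by(.data$.win) |>
    dplyr::summarise(counter_minutes = sum(.data$minutes), .groups = "drop")
  windows$counter_minutes <- 0
  windows$counter_minutes[counters$.win] <- counters$counter_minutes

  logs$minutes[masked] <- NA_real_
  logs$connected[masked] <- 0L
  list(logs = logs, windows = windows)
}

empty_windows <- function() {
  tibble::tibble(
    user_id = character(), date = as.Date(character()),
    start_hour = integer(), end_hour = integer(), counter_minutes = numeric()
  )
}

#' Generate a synthetic hearing aid usage cohort with ground truth
#'
#' Produces an hour-resolved, per-ear usage log for a cohort of simulated
#' users together with the ground truth every downstream stage can be
#' checked against: each user's group (A/B/C/noise), each day's archetype,
#' and the disconnection windows with their minute counters. Left- and
#' right-ear records differ by a small per-hour perturbation so binaural
#' resolution is exercised. The output is byte-reproducible given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `wearday_cohort`: a list with tibbles `logs`
#'   (`user_id`, `date`, `hour`, `side`, `minutes`, `connected`), `windows`
#'   (`user_id`, `date`, `start_hour`, `end_hour`, `counter_minutes`),
#'   `truth` (`user_id`, `group`, `date`, `day_type`) and `users`
#'   (`user_id`, `group`, mixture columns).
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  templates <- archetype_templates()
  tpl <- setNames(
    lapply(seq_len(nrow(templates)), function(i) {
      x <- as.list(templates[i, ])
      x$mean_curve <- x$mean_curve[[1]]
      x
    }),
    templates$name
  )
  n <- config$n_users
  if (n == 0) {
    return(structure(
      list(
        logs = tibble::tibble(
          user_id = character(), date = as.Date(character()), hour = integer(),
          side = character(), minutes = numeric(), connected = integer()
        ),
        windows = empty_windows(),
        truth = tibble::tibble(
          user_id = character(), group = character(),
          date = as.Date(character()), day_type = character()
        ),
        users = tibble::tibble(user_id = character(), group = character())
      ),
      class = "wearday_cohort"
    ))
  }

  user_id <- sprintf("u%05d", seq_len(n))
  groups <- sample(names(config$group_weights), n, replace = TRUE,
                   prob = config$group_weights)
  n_days <- pmin(120L, pmax(1L, as.integer(round(
    rnorm(n, config$days_per_user[1], config$days_per_user[2])
  ))))
  mixtures <- t(vapply(groups, sample_user_mixture, numeric(3), config = config))
  period_start <- as.Date("2022-01-01")

  day_user <- character(0); day_date <- as.Date(character(0))
  day_type <- character(0)
  type_names <- archetype_levels()
  per_user_days <- vector("list", n)
  for (i in seq_len(n)) {
    nd <- n_days[i]
    start_off <- sample.int(120L - nd + 1L, 1) - 1L
    dates <- period_start + start_off + seq_len(nd) - 1L
    if (!is.null(config$day_type_weights_global)) {
      types <- sample(day_type_levels(), nd, replace = TRUE,
                      prob = config$day_type_weights_global)
    } else {
      atypical <- runif(nd) < config$atypical_day_rate
      types <- character(nd)
      wk_mult <- config$weekend_multiplier
      if (wk_mult != 1) {
        weekend <- format(dates, "%u") %in% c("6", "7")
        for (j in seq_len(nd)) {
          w <- mixtures[i, ]
          if (weekend[j]) w <- w * c(1, wk_mult, wk_mult)
          types[j] <- sample(type_names, 1, prob = w / sum(w))
        }
      } else {
        types <- sample(type_names, nd, replace = TRUE, prob = mixtures[i, ])
      }
      types[atypical] <- "atypical"
    }
    per_user_days[[i]] <- list(dates = dates, types = types)
  }
  day_user <- rep(user_id, n_days)
  day_date <- as.Date(unlist(lapply(per_user_days, function(x) x$dates)),
                      origin = "1970-01-01")
  day_type <- unlist(lapply(per_user_days, function(x) x$types))
  nd_total <- length(day_type)

  left <- matrix(0, nd_total, 18)
  for (j in seq_len(nd_total)) {
    left[j, ] <- sample_day_vector(day_type[j], tpl[[day_type[j]]])
  }
  right <- pmin(pmax(left + matrix(rnorm(nd_total * 18, 0, 2), nd_total, 18) *
                       (left > 0), 0), 60)

  idx <- rep(seq_len(nd_total), each = 18)
  hours <- rep(HOURS, nd_total)
  logs <- tibble::tibble(
    user_id = rep(day_user[idx], 2),
    date = rep(day_date[idx], 2),
    hour = rep(hours, 2),
    side = rep(c("L", "R"), each = nd_total * 18),
    minutes = c(as.vector(t(left)), as.vector(t(right))),
    connected = 1L
  )

  disc <- inject_disconnections(logs, config)
  truth <- tibble::tibble(
    user_id = day_user,
    group = rep(groups, n_days),
    date = day_date,
    day_type = day_type
  )
  users <- tibble::tibble(
    user_id = user_id, group = groups,
    p_full_day = mixtures[, 1], p_afternoon = mixtures[, 2],
    p_sporadic_evening = mixtures[, 3]
  )
  structure(
    list(logs = disc$logs, windows = disc$windows, truth = truth, users = users),
    class = "wearday_cohort"
  )
}

#' @export
print.wearday_cohort <- function(x, ...) {
  cat("<wearday_cohort>\n")
  cat("  users: ", nrow(x$users), "\n", sep = "")
  cat("  logged days: ", nrow(x$truth), "\n", sep = "")
  cat("  log rows: ", nrow(x$logs), "\n", sep = "")
  cat("  disconnection windows: ", nrow(x$windows), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to delimited text files
#'
#' Writes `logs.csv`, `windows.csv` and `truth.csv` (schemas as in
#' [generate_cohort()]) into `dir`.
#'
#' @param cohort A `wearday_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$logs, file.path(dir, "logs.csv"), row.names = FALSE)
  utils::write.csv(cohort$windows, file.path(dir, "windows.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
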