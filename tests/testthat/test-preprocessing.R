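test_that("binaural resolution takes the per-hour maximum", {
  logs <- logs_for_day("u1", "2022-01-03", left = rep(40, 18), right = rep(55, 18))
  res <- resolve_binaural(logs)
  expect_equal(res$minutes, rep(55, 18))

  logs2 <- logs_for_day("u1", "2022-01-03", left = rep(60, 18))
  expect_equal(resolve_binaural(logs2)$minutes, rep(60, 18))

  # elementwise dominance and commutativity on random series
  set.seed(4)
  l <- runif(18, 0, 60); r <- runif(18, 0, 60)
  a <- resolve_binaural(logs_for_day("u", "2022-02-01", l, r))
  b <- resolve_binaural(logs_for_day("u", "2022-02-01", r, l))
  expect_true(all(a$minutes >= l & a$minutes >= r))
  expect_equal(a$minutes, b$minutes)
})

test_that("disconnection imputation follows the counter rules exactly", {
  # full-time use is assigned as-is
  full <- impute_disconnection(10, 11, 120)
  expect_equal(full$minutes, c(60, 60))
  expect_equal(full$flag, "full_time")

  # on-off use is spread evenly
  onoff <- impute_disconnection(10, 11, 60)
  expect_equal(onoff$minutes, c(30, 30))
  expect_equal(onoff$flag, "on_off")

  zero <- impute_disconnection(12, 12, 0)
  expect_equal(zero$minutes, 0)
  expect_equal(zero$flag, "on_off")

  expect_error(impute_disconnection(10, 11, 121), "counter_minutes")
  expect_error(impute_disconnection(5, 7, 10), "window")

  # totals conserved exactly, fractional minutes kept
  set.seed(9)
  for (i in 1:25) {
    s <- sample(6:22, 1); e <- sample(s:23, 1)
    cm <- runif(1, 0, 60 * (e - s + 1))
    out <- impute_disconnection(s, e, cm)
    expect_equal(sum(out$minutes), cm, tolerance = 1e-12)
  }
})

test_that("the five filters remove the right days in the right order", {
  d1 <- day_row("uA", "2022-01-03", flat_day(12))      # clean
  d2 <- day_row("uA", "2022-01-04", rep(c(10, 0), 9))  # total 90 min, kept
  d3 <- day_row("uA", "2022-01-05", c(59 / 3, 59 / 3, 59 / 3, rep(0, 15)))  # 59 min
  d4 <- day_row("uA", "2022-01-06", c(70, rep(10, 17)))  # malformed hour
  d5 <- day_row("uA", "2022-01-07", flat_day(3))         # has long on-off window
  extras <- dplyr::bind_rows(lapply(8:17, function(i) {
    day_row("uA", sprintf("2022-01-%02d", i), flat_day(10))
  }))
  days <- day_rows(d1, d2, d3, d4, d5, extras)
  win <- tibble::tibble(
    user_id = "uA", date = as.Date("2022-01-07"),
    start_hour = 9L, end_hour = 11L, counter_minutes = 90
  )
  out <- clean_days(days, win)
  expect_equal(out$audit$rules$days_removed,
               c(1L, 1L, 1L, 0L, 0L))
  expect_equal(nrow(out$days), 12)
  expect_false(as.Date("2022-01-05") %in% out$days$date)
  expect_false(as.Date("2022-01-06") %in% out$days$date)
  expect_false(as.Date("2022-01-07") %in% out$days$date)

  # a full-time window of any length does not disqualify the day
  win_full <- tibble::tibble(
    user_id = "uA", date = as.Date("2022-01-08"),
    start_hour = 9L, end_hour = 12L, counter_minutes = 240
  )
  out2 <- clean_days(days, dplyr::bind_rows(win, win_full))
  expect_true(as.Date("2022-01-08") %in% out2$days$date)

  # exactly 60 minutes of use is kept (boundary)
  d60 <- day_row("uB", "2022-01-03", c(60, rep(0, 17)))
  out3 <- clean_days(day_rows(d60), empty_windows_tbl())
  expect_equal(out3$audit$rules$days_removed[3], 0L)
  # but uB then fails the 10-day rule
  expect_equal(out3$audit$rules$days_removed[5], 1L)
  expect_equal(nrow(out3$days), 0)
})

test_that("users with fewer than 10 retained days are dropped entirely", {
  mk_user <- function(u, n) {
    dplyr::bind_rows(lapply(seq_len(n), function(i) {
      day_row(u, as.Date("2022-01-01") + i, flat_day(10))
    }))
  }
  days <- day_rows(mk_user("u1", 9), mk_user("u2", 10))
  out <- clean_days(days, empty_windows_tbl())
  expect_setequal(unique(out$days$user_id), "u2")
  expect_equal(out$audit$rules$days_removed[5], 9L)
  expect_equal(out$audit$users_dropped, "u1")
})

test_that("filtering is idempotent and audits balance", {
  fx <- small_cohort()
  audit <- fx$prep$audit
  expect_equal(audit$n_retained + sum(audit$rules$days_removed), audit$n_input)
  again <- clean_days(fx$prep$days, fx$cohort$windows)
  expect_equal(again$days, fx$prep$days)
  expect_equal(sum(again$audit$rules$days_removed[c(2, 3, 5)]), 0)
})

test_that("the day matrix is sorted, 18 columns wide, and in range", {
  fx <- small_cohort()
  days <- fx$days
  expect_equal(names(days), c("user_id", "date", paste0("h", 6:23)))
  expect_false(is.unsorted(days$user_id))
  m <- day_matrix(days)
  expect_equal(ncol(m), 18)
  expect_true(all(m >= 0 & m <= 60))
  expect_true(all(rowSums(m) >= 60))

  empty <- build_day_matrix(days[0, ])
  expect_equal(nrow(empty), 0)
  expect_equal(ncol(day_matrix(empty)), 18)
})

test_that("preprocessing imputes windows into the day vectors", {
  logs <- dplyr::bind_rows(
    logs_for_day("u1", "2022-01-03", rep(30, 18)),
    lapply(4:13, function(i) {
      logs_for_day("u1", sprintf("2022-01-%02d", i), flat_day(10))
    })
  )
  # mask two hours, counter says 60 minutes of on-off use
  masked <- logs$date == as.Date("2022-01-03") & logs$hour %in% 14:15
  logs$minutes[masked] <- NA
  logs$connected[masked] <- 0L
  win <- tibble::tibble(
    user_id = "u1", date = as.Date("2022-01-03"),
    start_hour = 14L, end_hour = 15L, counter_minutes = 60
  )
  out <- preprocess_logs(logs, win)
  day <- out$days[out$days$date == as.Date("2022-01-03"), ]
  expect_equal(day$h14, 30)
  expect_equal(day$h15, 30)
  expect_equal(day$h13, 30)

  expect_error(preprocess_logs(logs[0, ], win), "empty input")
})
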