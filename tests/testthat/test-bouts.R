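test_that("strict bout detection honours the 10-minute rule", {
  expect_equal(nrow(detect_bouts(rep(TRUE, 9))), 0L)        # one short

  b <- detect_bouts(rep(c(FALSE, TRUE, FALSE), c(5, 12, 5)))
  expect_equal(nrow(b), 1L)
  expect_equal(b$start, 6L)
  expect_equal(b$end, 18L)          # half-open: covers minutes 6..17
  expect_equal(b$duration, 12L)

  expect_equal(nrow(detect_bouts(rep(TRUE, 10))), 1L)       # boundary
})

test_that("tolerant mode bridges short interruptions; strict does not", {
  x <- rep(c(TRUE, FALSE, TRUE), c(6, 1, 6))
  expect_equal(nrow(detect_bouts(x)), 0L)
  b <- detect_bouts(x, bout_definition(10, 1, "tolerant"))
  expect_equal(b$duration, 13L)     # interruption counted inside the bout

  # two interruptions need tolerance 2
  y <- rep(c(TRUE, FALSE, TRUE, FALSE, TRUE), c(4, 1, 4, 1, 4))
  expect_equal(nrow(detect_bouts(y, bout_definition(10, 1, "tolerant"))), 0L)
  expect_equal(detect_bouts(y, bout_definition(10, 2, "tolerant"))$duration,
               14L)

  # a bout never starts or ends on an interruption
  z <- c(FALSE, rep(TRUE, 11), FALSE, FALSE)
  b <- detect_bouts(z, bout_definition(10, 2, "tolerant"))
  expect_equal(b$start, 2L)
  expect_equal(b$end, 13L)
})

test_that("strict mode equals tolerant mode with zero tolerance", {
  set.seed(23)
  for (k in 1:200) {
    x <- runif(sample(15:120, 1)) < runif(1, 0.3, 0.9)
    expect_equal(detect_bouts(x, bout_definition(10)),
                 detect_bouts(x, bout_definition(10, 0, "tolerant")))
  }
})

test_that("bout minutes are monotone in the interruption tolerance", {
  set.seed(29)
  for (k in 1:200) {
    x <- runif(sample(30:150, 1)) < runif(1, 0.4, 0.9)
    mins <- vapply(0:3, function(tol) {
      sum(detect_bouts(x, bout_definition(10, tol, "tolerant"))$duration)
    }, numeric(1))
    expect_true(all(diff(mins) >= 0))
  }
})

test_that("detector agrees with the all-windows brute-force oracle", {
  set.seed(31)
  for (k in 1:300) {
    len <- sample(15:120, 1)
    x <- runif(len) < runif(1, 0.2, 0.95)
    md <- sample(c(5L, 8L, 10L), 1)
    tol <- sample(0:2, 1)
    defn <- bout_definition(md, tol, if (tol > 0) "tolerant" else "strict")
    expect_equal(as.data.frame(detect_bouts(x, defn)),
                 as.data.frame(brute_force_bouts(x, md, tol)))
  }
})

test_that("daily accumulation: saturated and fragmented extremes", {
  prof <- mk_profile("S1")
  sat <- mk_records(rep(4, 1440), subject_id = "S1")
  d <- daily_mvpa(sat, prof, "acsm_aha")
  expect_equal(d$nonbout_minutes, 1440L)
  expect_equal(d$bout_minutes, 1440L)
  expect_equal(d$bout_count, 1L)

  # 30 isolated MVPA minutes separated by rest: all counted without bouts,
  # none within bouts
  mets <- rep(1, 1440)
  mets[seq(1, by = 20, length.out = 30)] <- 5
  frag <- mk_records(mets, subject_id = "S1")
  d <- daily_mvpa(frag, prof, "acsm_aha")
  expect_equal(d$nonbout_minutes, 30L)
  expect_equal(d$bout_minutes, 0L)
})

test_that("non-wear minutes terminate runs", {
  # 20 above-threshold minutes, but the armband was off for minute 11
  wear <- rep(TRUE, 1440); wear[11] <- FALSE
  recs <- mk_records(rep(c(5, 1), c(20, 1420)), wear = wear,
                     subject_id = "S1")
  d <- daily_mvpa(recs, mk_profile("S1"), "acsm_aha")
  expect_equal(d$nonbout_minutes, 19L)   # the off-body minute is excluded
  # minutes 1..10 form a bout; the 9-minute run after the gap does not
  expect_equal(d$bout_minutes, 10L)
  expect_equal(d$bout_count, 1L)
})

test_that("daily_mvpa equals an independent per-day recount", {
  coh <- small_cohort(6, 6)
  daily <- daily_mvpa(coh$records, coh$profiles, c("acsm_aha", "vo2r_50"))
  recs <- dplyr::mutate(coh$records,
                        date = as.Date(.data$timestamp, tz = "UTC"),
                        minute = as.POSIXlt(.data$timestamp)$hour * 60L +
                          as.POSIXlt(.data$timestamp)$min)
  set.seed(41)
  pick <- daily[sample(nrow(daily), 40), ]
  for (r in seq_len(nrow(pick))) {
    row <- pick[r, ]
    day <- dplyr::filter(recs, .data$subject_id == row$subject_id,
                         .data$date == row$date)
    v <- rep(FALSE, 1440L)
    v[day$minute[day$wear & day$mets >= row$threshold] + 1L] <- TRUE
    oracle <- brute_force_bouts(v, 10, 0)
    expect_equal(row$nonbout_minutes, sum(v))
    expect_equal(row$bout_minutes, as.integer(sum(oracle$duration)))
    expect_equal(row$bout_count, nrow(oracle))
  }
})

test_that("fast strict path and windowed path give identical results", {
  coh <- small_cohort(5, 5)
  strict <- daily_mvpa(coh$records, coh$profiles, "acsm_aha",
                       bout_definition(10))
  windowed <- daily_mvpa(coh$records, coh$profiles, "acsm_aha",
                         bout_definition(10, 1, "tolerant"))
  # tolerant(1) can only add minutes relative to strict
  expect_true(all(windowed$bout_minutes >= strict$bout_minutes))
  # and with the windowed engine forced through tolerance 0 internals:
  w0 <- actibout:::count_bouts_windowed(
    dplyr::inner_join(
      dplyr::mutate(dplyr::filter(coh$records, .data$wear),
                    date = as.Date(.data$timestamp, tz = "UTC"),
                    minute = as.POSIXlt(.data$timestamp)$hour * 60L +
                      as.POSIXlt(.data$timestamp)$min),
      dplyr::distinct(add_met_thresholds(coh$profiles, "acsm_aha"),
                      .data$subject_id, .data$threshold),
      by = "subject_id") |>
      dplyr::mutate(mvpa = .data$mets >= .data$threshold),
    bout_definition(10, 0, "tolerant"))
  cmp <- dplyr::inner_join(
    strict, w0, by = c("subject_id", "date"),
    suffix = c("_fast", "_win"))
  expect_equal(cmp$bout_minutes_fast, cmp$bout_minutes_win)
  expect_equal(cmp$nonbout_minutes_fast, cmp$nonbout_minutes_win)
})

test_that("per-subject summaries average over valid days only", {
  week <- as.Date("2024-03-04") + 0:6
  daily <- tibble::tibble(
    subject_id = "S1",
    date = week[1:2],
    scheme = "acsm_aha", threshold = 3,
    nonbout_minutes = c(40L, 60L),
    bout_minutes = c(20L, 40L),
    bout_count = c(2L, 3L)
  )
  days <- mk_days(rep(1440, 7), week) |>
    dplyr::mutate(subject_id = "S1", .before = 1)
  ok <- tibble::tibble(subject_id = "S1", valid = TRUE,
                       reason = NA_character_)
  s <- summarize_mvpa(daily, days, ok)
  expect_equal(s$mvpa_nonbout, 50)
  expect_equal(s$mvpa_bout, 30)
  expect_equal(s$fold_ratio, 50 / 30)

  # single valid day: the summary is that day
  days1 <- mk_days(c(1440, rep(0, 6)), week) |>
    dplyr::mutate(subject_id = "S1", .before = 1)
  s1 <- summarize_mvpa(daily, days1, ok)
  expect_equal(s1$mvpa_nonbout, 40)

  # no valid subjects is a contract violation
  bad <- tibble::tibble(subject_id = "S1", valid = FALSE,
                        reason = "valid_days")
  expect_error(summarize_mvpa(daily, days, bad), "no valid assessments")
})

test_that("fold ratio is undefined at zero bout MVPA", {
  week <- as.Date("2024-03-04")
  daily <- tibble::tibble(subject_id = "S1", date = week,
                          scheme = "acsm_aha", threshold = 3,
                          nonbout_minutes = 25L, bout_minutes = 0L,
                          bout_count = 0L)
  days <- mk_days(1440, week) |> dplyr::mutate(subject_id = "S1", .before = 1)
  ok <- tibble::tibble(subject_id = "S1", valid = TRUE, reason = NA_character_)
  expect_true(is.na(summarize_mvpa(daily, days, ok)$fold_ratio))
})

test_that("healthy cohort bout/non-bout fold ratio sits in the 2-4 band", {
  coh <- generate_cohort(cohort_spec(n_healthy = 50, n_copd = 0, seed = 55))
  days <- summarize_days(coh$records)
  ass <- is_valid_assessment(days)
  s <- summarize_mvpa(daily_mvpa(coh$records, coh$profiles, "acsm_aha"),
                      days, ass)
  med <- median(s$fold_ratio, na.rm = TRUE)
  expect_gt(med, 2)
  expect_lt(med, 4)
})
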