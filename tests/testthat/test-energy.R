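test_that("MET-to-kcal conversion follows the 1 kcal/kg/h convention", {
  expect_equal(mets_to_kcal(1, 70, 60), 70)
  expect_equal(mets_to_kcal(0, 90, 500), 0)
  expect_equal(mets_to_kcal(3.5, 80, 30), 140)
  # configurable coefficient scales linearly
  expect_equal(mets_to_kcal(2, 70, 60, kcal_per_met_hour = 1.05),
               2 * 70 * 1.05)
})

test_that("Harris-Benedict predictions match the published coefficients", {
  man <- mk_profile(sex = "male", weight_kg = 70, height_cm = 175, age = 62)
  woman <- mk_profile(sex = "female", weight_kg = 70, height_cm = 175,
                      age = 62)
  # hand arithmetic on the 1919 coefficients
  expect_equal(ree_harris_benedict(man),
               66.473 + 13.7516 * 70 + 5.0033 * 175 - 6.755 * 62)
  expect_equal(ree_harris_benedict(man), 1485.8525)
  expect_equal(ree_harris_benedict(woman),
               655.0955 + 9.5634 * 70 + 1.8496 * 175 - 4.6756 * 62)
  expect_equal(ree_harris_benedict(woman), 1358.3263)

  # linear in weight: +1 kg adds exactly the weight coefficient
  heavier <- mk_profile(weight_kg = 71)
  expect_equal(ree_harris_benedict(heavier) -
                 ree_harris_benedict(mk_profile(weight_kg = 70)),
               13.7516)

  # revised (Roza-Shizgal) coefficients behind the flag
  expect_equal(ree_harris_benedict(man, "revised"),
               88.362 + 13.397 * 70 + 4.799 * 175 - 5.677 * 62)
})

test_that("sleep-measured REE matches its closed form", {
  # 8 h of flagged sleep at 0.9 METs, 70 kg: 0.9 * 70 * 24 kcal/day
  recs <- dplyr::bind_rows(
    mk_records(rep(0.9, 480), start_min = 0, sleep = TRUE),
    mk_records(rep(1.5, 960), start_min = 480)
  )
  ree <- ree_from_sleep(recs, mk_profile())
  expect_equal(as.numeric(ree), 0.9 * 70 * 24)
  expect_identical(attr(ree, "source"), "sleep_measured")

  # sleeping at exactly 1 MET equals a resting day of minute conversions
  recs1 <- dplyr::bind_rows(
    mk_records(rep(1, 480), sleep = TRUE),
    mk_records(rep(1.5, 960), start_min = 480)
  )
  expect_equal(as.numeric(ree_from_sleep(recs1, mk_profile())),
               mets_to_kcal(1, 70, 1440))
})

test_that("only the longest night block between 20:00 and 10:00 counts", {
  # 300-minute block from midnight plus a 150-minute afternoon nap:
  # the nap (13:00-15:30) is outside the night window
  recs <- dplyr::bind_rows(
    mk_records(rep(0.9, 300), start_min = 0, sleep = TRUE),
    mk_records(rep(1.4, 480), start_min = 300),
    mk_records(rep(1.1, 150), start_min = 780, sleep = TRUE),
    mk_records(rep(1.4, 510), start_min = 930)
  )
  ree <- ree_from_sleep(recs, mk_profile())
  expect_equal(as.numeric(ree), 0.9 * 70 * 24)
})

test_that("too little sleep falls back to Harris-Benedict with a warning", {
  recs <- dplyr::bind_rows(
    mk_records(rep(0.9, 60), sleep = TRUE),     # < 120 min
    mk_records(rep(1.4, 1380), start_min = 60)
  )
  expect_warning(ree <- ree_from_sleep(recs, mk_profile()),
                 "falling back to Harris-Benedict")
  expect_equal(as.numeric(ree), 1485.8525)
  expect_identical(attr(ree, "source"), "harris_benedict")
})

# a valid 7-day constant-intensity week for one subject
constant_week <- function(mets_value, subject_id = "S1", sleep_mets = NULL) {
  dplyr::bind_rows(lapply(0:6, function(k) {
    date <- as.Date("2024-03-04") + k
    if (is.null(sleep_mets)) {
      mk_records(rep(mets_value, 1440), date = date, subject_id = subject_id)
    } else {
      dplyr::bind_rows(
        mk_records(rep(sleep_mets, 480), date = date, sleep = TRUE,
                   subject_id = subject_id),
        mk_records(rep(mets_value, 960), date = date, start_min = 480,
                   subject_id = subject_id)
      )
    }
  }))
}

test_that("a whole week at 1 MET with sleep-measured REE gives PAL 1", {
  recs <- constant_week(1, sleep_mets = 1)
  prof <- mk_profile("S1")
  days <- summarize_days(recs)
  ass <- is_valid_assessment(days)
  e <- summarize_energy(recs, prof, days, ass)
  expect_equal(e$pal, 1)
  expect_equal(e$tee_kcal, e$ree_kcal)
  expect_identical(e$ree_source, "sleep_measured")
})

test_that("non-wear time is imputed at the resting rate", {
  # waking-hours subject: 720 worn minutes at 2 METs, the rest off-body
  prof <- mk_profile("S1", wear_protocol = "waking_hours")
  recs <- dplyr::bind_rows(lapply(0:6, function(k) {
    mk_records(rep(2, 720), date = as.Date("2024-03-04") + k,
               start_min = 480, subject_id = "S1")
  }))
  days <- summarize_days(recs)
  ass <- is_valid_assessment(days)
  e <- summarize_energy(recs, prof, days, ass)
  ree <- ree_harris_benedict(prof)
  expect_equal(e$ree_kcal, ree)
  expect_equal(e$tee_kcal, 720 * 2 * 70 / 60 + 720 * ree / 1440)
  expect_identical(e$ree_source, "harris_benedict")
})

test_that("TEE is monotone in any single minute's METs", {
  prof <- mk_profile("S1", wear_protocol = "waking_hours")
  base <- dplyr::bind_rows(lapply(0:6, function(k) {
    mk_records(rep(1.5, 900), date = as.Date("2024-03-04") + k,
               subject_id = "S1")
  }))
  days <- summarize_days(base)
  ass <- is_valid_assessment(days)
  e0 <- summarize_energy(base, prof, days, ass)
  bumped <- base
  bumped$mets[123] <- bumped$mets[123] + 2
  e1 <- summarize_energy(bumped, prof, days, ass)
  expect_gt(e1$tee_kcal, e0$tee_kcal)
})

test_that("a PAL below 1 raises a data-quality warning", {
  prof <- mk_profile("S1", wear_protocol = "waking_hours")
  recs <- dplyr::bind_rows(lapply(0:6, function(k) {
    mk_records(rep(0.2, 1440), date = as.Date("2024-03-04") + k,
               subject_id = "S1")
  }))
  days <- summarize_days(recs)
  ass <- is_valid_assessment(days)
  expect_warning(e <- summarize_energy(recs, prof, days, ass), "PAL < 1")
  expect_lt(e$pal, 1)
})

test_that("healthy synthetic cohort PAL centres near the 1.64 target", {
  coh <- generate_cohort(cohort_spec(n_healthy = 40, n_copd = 0, seed = 61))
  days <- summarize_days(coh$records)
  ass <- is_valid_assessment(days)
  e <- summarize_energy(coh$records, coh$profiles, days, ass)
  expect_lt(abs(median(e$pal) - 1.64), 0.12)
})
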