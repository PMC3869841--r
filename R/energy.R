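#' Convert METs to kilocalories
#'
#' Uses the compendium convention 1 MET = 1 kcal per kg body weight per
#' hour, so `kcal = mets * weight_kg * minutes / 60`. The coefficient is
#' configurable for sensitivity analyses.
#'
#' @param mets MET value(s).
#' @param weight_kg Body weight in kg.
#' @param minutes Duration in minutes (default 1, i.e. one epoch).
#' @param kcal_per_met_hour Conversion coefficient (default 1).
#' @return Energy in kcal.
#' @export
#' @examples
#' mets_to_kcal(1, 70, 60)    # 70 kcal: one hour at rest for 70 kg
#' mets_to_kcal(3.5, 80, 30)  # 140 kcal
mets_to_kcal <- function(mets, weight_kg, minutes = 1, kcal_per_met_hour = 1) {
  mets * weight_kg * (minutes / 60) * kcal_per_met_hour
}

#' Predicted resting energy expenditure (Harris-Benedict)
#'
#' Sex-specific Harris-Benedict prediction of resting energy expenditure
#' (kcal/day) from weight, height and age. The default is the original
#' 1919 coefficients; the revised Roza-Shizgal (1984) coefficients are
#' available via `variant = "revised"`.
#'
#' @param profiles Profiles tibble with `sex`, `weight_kg`, `height_cm`,
#'   `age`.
#' @param variant `"original"` (default) or `"revised"`.
#' @return Numeric vector, kcal/day, one value per profile row.
#' @export
#' @examples
#' p <- tibble::tibble(sex = c("male", "female"), weight_kg = 70,
#'                     height_cm = 175, age = 62L)
#' ree_harris_benedict(p)
ree_harris_benedict <- function(profiles, variant = c("original", "revised")) {
  variant <- match.arg(variant)
  assert_columns(profiles, c("sex", "weight_kg", "height_cm", "age"),
                 "profiles")
  w <- profiles$weight_kg; h <- profiles$height_cm; a <- profiles$age
  male <- profiles$sex == "male"
  if (variant == "original") {
    if_else(male,
            66.473 + 13.7516 * w + 5.0033 * h - 6.755 * a,
            655.0955 + 9.5634 * w + 1.8496 * h - 4.6756 * a)
  } else {
    if_else(male,
            88.362 + 13.397 * w + 4.799 * h - 5.677 * a,
            447.593 + 9.247 * w + 3.098 * h - 4.330 * a)
  }
}

#' Measured resting energy expenditure from whole-night sleep
#'
#' For subjects wearing the monitor around the clock, resting energy
#' expenditure can be measured rather than predicted: the mean per-minute
#' energy expenditure over sleep-flagged wear minutes, scaled to 24 h.
#' The night is operationalized as the longest sleep-flagged block per
#' calendar day falling between 20:00 and 10:00; blocks from all days are
#' pooled. With fewer than `min_sleep_minutes` pooled sleep minutes the
#' function falls back to [ree_harris_benedict()] with a warning.
#'
#' @param records One subject's minute records (`timestamp, mets, wear,
#'   sleep`).
#' @param profile One-row profiles tibble for the same subject.
#' @param min_sleep_minutes Minimum pooled sleep minutes (default 120).
#' @param kcal_per_met_hour Passed to [mets_to_kcal()].
#' @param tz Time zone of the calendar-day boundary.
#' @return REE in kcal/day with attribute `source` set to
#'   `"sleep_measured"` or `"harris_benedict"`.
#' @export
ree_from_sleep <- function(records, profile, min_sleep_minutes = 120,
                           kcal_per_met_hour = 1, tz = "UTC") {
  assert_columns(records, c("timestamp", "mets", "wear", "sleep"), "records")
  stopifnot(nrow(profile) == 1)
  night <- records |>
    filter(.data$wear, .data$sleep) |>
    mutate(
      date = as.Date(.data$timestamp, tz = tz),
      minute = minute_of_day(.data$timestamp)
    ) |>
    filter(.data$minute >= 1200L | .data$minute < 600L)

  pooled <- numeric(0)
  if (nrow(night) > 0) {
    blocks <- night |>
      arrange(.data$timestamp) |>
      group_by(.data$date) |>
      dplyr::group_map(function(d, key) {
        brk <- cumsum(c(TRUE, diff(d$minute) != 1L))
        lens <- tabulate(brk)
        d$mets[brk == which.max(lens)]
      })
    pooled <- unlist(blocks)
  }
  if (length(pooled) < min_sleep_minutes) {
    warn(sprintf(
      "subject %s: only %d sleep-flagged night minutes (< %d); falling back to Harris-Benedict REE",
      profile$subject_id %||% "?", length(pooled), min_sleep_minutes
    ))
    ree <- ree_harris_benedict(profile)
    attr(ree, "source") <- "harris_benedict"
    return(ree)
  }
  per_min <- mets_to_kcal(mean(pooled), profile$weight_kg, 1, kcal_per_met_hour)
  ree <- per_min * 1440
  attr(ree, "source") <- "sleep_measured"
  ree
}

#' Total energy expenditure and physical activity level
#'
#' Daily total energy expenditure (TEE) is the measured energy expenditure
#' over worn minutes plus predicted energy expenditure for non-wear time,
#' imputed at the resting rate: `TEE = sum(wear-minute kcal) +
#' non_wear_minutes * REE / 1440`. The resting energy expenditure (REE)
#' source follows the wear protocol: around-the-clock wearers
#' (`full_day`) use the whole-night sleeping energy expenditure
#' ([ree_from_sleep()]), waking-hours wearers use the Harris-Benedict
#' prediction. TEE is averaged over valid days only, and
#' `PAL = TEE / REE`. A PAL below 1 is flagged with a data-quality
#' warning (it implies measured expenditure below resting).
#'
#' @param records Minute records (`subject_id, timestamp, mets, wear,
#'   sleep`).
#' @param profiles Profiles tibble.
#' @param days Day summaries from [summarize_days()].
#' @param assessments Output of [is_valid_assessment()]; only valid
#'   subjects are summarized.
#' @param hb_variant Harris-Benedict coefficient set, see
#'   [ree_harris_benedict()].
#' @param kcal_per_met_hour MET-to-kcal coefficient.
#' @param tz Time zone of the calendar-day boundary.
#' @return Tibble `subject_id, tee_kcal, ree_kcal, ree_source, pal`.
#' @export
summarize_energy <- function(records, profiles, days, assessments,
                             hb_variant = "original",
                             kcal_per_met_hour = 1, tz = "UTC") {
  assert_columns(records, c("subject_id", "timestamp", "mets", "wear"),
                 "records")
  valid_subjects <- assessments$subject_id[assessments$valid]
  if (length(valid_subjects) == 0) {
    abort("no valid assessments: every subject fails the wear-time criteria")
  }
  if (!"sleep" %in% names(records)) records$sleep <- FALSE
  valid_days <- days |>
    filter(.data$valid_day, .data$subject_id %in% valid_subjects)

  purrr::map(valid_subjects, function(id) {
    prof <- profiles |> filter(.data$subject_id == id)
    recs <- records |> filter(.data$subject_id == id)
    vdays <- valid_days |> filter(.data$subject_id == id)
    if (nrow(vdays) == 0) return(NULL)

    if (prof$wear_protocol == "full_day") {
      ree <- ree_from_sleep(recs, prof, kcal_per_met_hour = kcal_per_met_hour,
                            tz = tz)
      ree_source <- attr(ree, "source")
    } else {
      ree <- ree_harris_benedict(prof, hb_variant)
      ree_source <- "harris_benedict"
    }
    ree <- as.numeric(ree)

    day_tee <- recs |>
      filter(.data$wear) |>
      mutate(date = as.Date(.data$timestamp, tz = tz)) |>
      semi_join(vdays, by = "date") |>
      group_by(.data$date) |>
      summarise(
        measured = sum(mets_to_kcal(.data$mets, prof$weight_kg, 1,
                                    kcal_per_met_hour)),
        wear_minutes = dplyr::n(),
        .groups = "drop"
      ) |>
      # valid days with zero wear rows cannot occur (valid => >= 720 wear
      # minutes), but non-wear imputation still applies to the remainder
      mutate(tee = .data$measured + (1440 - .data$wear_minutes) * ree / 1440)

    tibble(
      subject_id = id,
      tee_kcal = mean(day_tee$tee),
      ree_kcal = ree,
      ree_source = ree_source,
      pal = mean(day_tee$tee) / ree
    )
  }) |>
    bind_rows() |>
    (\(out) {
      low <- out$pal < 1
      if (any(low)) {
        warn(sprintf("PAL < 1 for %d subject(s): check wear flags and METs",
                     sum(low)))
      }
      out
    })()
}
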