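#' Per-day wear-time accounting
#'
#' Summarizes every calendar day touched by a trace: worn minutes (records
#' with `wear = TRUE`; missing epochs count as non-wear), weekend status
#' (Saturday or Sunday) and the valid-day flag (at least `min_wear_hours`
#' of wear). Days are local calendar days with a midnight boundary.
#'
#' @param records Minute-record tibble with `timestamp` and `wear`; an
#'   optional `subject_id` column yields per-subject summaries.
#' @param min_wear_hours Minimum wear time for a valid day (default 12 h).
#' @param tz Time zone for the calendar-day boundary.
#' @return A tibble `subject_id (if present), date, wear_minutes,
#'   is_weekend, valid_day`, ordered by subject and date.
#' @export
summarize_days <- function(records, min_wear_hours = 12, tz = "UTC") {
  assert_columns(records, c("timestamp", "wear"), "records")
  grouped <- "subject_id" %in% names(records)
  df <- records |>
    mutate(date = as.Date(.data$timestamp, tz = tz))
  keys <- c(if (grouped) "subject_id", "date")
  out <- df |>
    group_by(across(all_of(keys))) |>
    summarise(wear_minutes = as.integer(sum(.data$wear)), .groups = "drop") |>
    mutate(
      is_weekend = is_weekend_date(.data$date),
      valid_day = .data$wear_minutes >= min_wear_hours * 60
    ) |>
    arrange(across(all_of(keys)))
  out
}

#' Valid-assessment filter
#'
#' An activity assessment is valid when the subject's set of valid days
#' (>= 12 h wear by default, see [summarize_days()]) contains the weekend
#' (both a Saturday and a Sunday when `weekend_days_required = 2`, the
#' default reading of "weekend days"; any one weekend day when `1`; none
#' required when `0`), at least `min_weekdays` weekdays, and at least
#' `min_valid_days` valid days in total. The returned reason names the
#' first failed criterion, checked in that order, so exclusion accounting
#' is exhaustive: every subject is valid or carries a reason.
#'
#' @param days Day summaries from [summarize_days()].
#' @param min_valid_days Minimum number of valid days (default 5).
#' @param min_weekdays Minimum number of valid weekdays (default 3).
#' @param weekend_days_required 0, 1 or 2 (default 2: both Saturday and
#'   Sunday must be valid).
#' @return A tibble `subject_id (if present), valid, reason` with reason
#'   `NA` for valid assessments and one of `"weekend_days"`, `"weekdays"`,
#'   `"valid_days"` otherwise.
#' @export
is_valid_assessment <- function(days, min_valid_days = 5, min_weekdays = 3,
                                weekend_days_required = 2) {
  assert_columns(days, c("date", "wear_minutes", "is_weekend", "valid_day"),
                 "day summaries")
  if (nrow(days) == 0) abort("day summaries are empty")
  grouped <- "subject_id" %in% names(days)
  one <- function(d) {
    v <- d[d$valid_day, , drop = FALSE]
    wd <- as.POSIXlt(v$date)$wday
    n_sat <- sum(wd == 6L)
    n_sun <- sum(wd == 0L)
    n_weekend_kinds <- (n_sat > 0) + (n_sun > 0)
    n_week <- sum(!v$is_weekend)
    reason <- if (n_weekend_kinds < weekend_days_required) {
      "weekend_days"
    } else if (n_week < min_weekdays) {
      "weekdays"
    } else if (nrow(v) < min_valid_days) {
      "valid_days"
    } else {
      NA_character_
    }
    tibble(valid = is.na(reason), reason = reason)
  }
  if (grouped) {
    days |>
      group_by(.data$subject_id) |>
      dplyr::group_modify(~ one(.x)) |>
      ungroup()
  } else {
    one(days)
  }
}
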