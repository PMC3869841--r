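#' Define what counts as an MVPA bout
#'
#' Guidelines require MVPA to be accumulated in bouts of at least ten
#' consecutive minutes above the MET cut-point. The strict definition
#' (`mode = "strict"`) takes maximal runs of above-threshold minutes of
#' length >= `min_duration`. The interruption-tolerant variant
#' (`mode = "tolerant"`) additionally allows up to `tolerance_minutes`
#' below-threshold minutes inside a qualifying window; a window starts and
#' ends on an above-threshold minute, and all of its minutes, including the
#' tolerated interruptions, count toward bout MVPA. Reported bouts are the
#' connected unions of overlapping qualifying windows, so bout minutes are
#' monotone in the tolerance; a long bout assembled by chained windows can
#' contain more than `tolerance_minutes` interruptions in total, but every
#' stretch of it is witnessed by a window with at most that many.
#'
#' @param min_duration Minimum bout length in minutes (default 10).
#' @param tolerance_minutes Allowed below-threshold minutes inside a bout
#'   (default 0; typical variant values 1-2). Only meaningful in tolerant
#'   mode.
#' @param mode `"strict"` or `"tolerant"`. `tolerant` with
#'   `tolerance_minutes = 0` is identical to `strict`.
#' @return A list of class `bout_definition`.
#' @export
bout_definition <- function(min_duration = 10, tolerance_minutes = 0,
                            mode = c("strict", "tolerant")) {
  mode <- match.arg(mode)
  if (min_duration < 1) abort("min_duration must be >= 1")
  if (tolerance_minutes < 0) abort("tolerance_minutes must be >= 0")
  if (mode == "strict" && tolerance_minutes > 0) {
    abort("tolerance_minutes > 0 requires mode = \"tolerant\"")
  }
  structure(
    list(min_duration = as.integer(min_duration),
         tolerance_minutes = as.integer(tolerance_minutes),
         mode = mode),
    class = "bout_definition"
  )
}

#' Detect MVPA bouts in one day of per-minute classifications
#'
#' Operates on a day's ordered sequence of per-minute MVPA indicators
#' (non-wear and missing minutes must already be `FALSE`). Returns
#' disjoint, ordered, half-open minute intervals. In tolerant mode, a
#' minute belongs to a bout when some qualifying window covers it (a
#' window of >= `min_duration` minutes that starts and ends above
#' threshold with at most `tolerance_minutes` interruptions); overlapping
#' windows merge into one bout. Bouts never cross the midnight boundary
#' because the input covers a single calendar day.
#'
#' @param mvpa Logical vector, one element per minute of the day (`NA`
#'   treated as `FALSE`).
#' @param defn A [bout_definition()].
#' @return A tibble `start, end, duration` where `start` is the 1-based
#'   index of the first bout minute and `end` is one past the last
#'   (`duration = end - start`).
#' @export
#' @examples
#' x <- rep(c(FALSE, TRUE, FALSE), c(5, 12, 5))
#' detect_bouts(x)                     # one 12-minute bout
#' y <- rep(c(TRUE, FALSE, TRUE), c(6, 1, 6))
#' detect_bouts(y)                                  # none: runs of 6
#' detect_bouts(y, bout_definition(10, 1, "tolerant"))  # one 13-minute bout
detect_bouts <- function(mvpa, defn = bout_definition()) {
  stopifnot(is.logical(mvpa))
  mvpa[is.na(mvpa)] <- FALSE
  empty <- tibble(start = integer(), end = integer(), duration = integer())
  n <- length(mvpa)
  if (n == 0 || !any(mvpa)) return(empty)

  if (defn$mode == "strict" || defn$tolerance_minutes == 0L) {
    r <- rle(mvpa)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= defn$min_duration
    return(tibble(
      start = starts[keep],
      end = ends[keep] + 1L,
      duration = r$lengths[keep]
    ))
  }

  tol <- defn$tolerance_minutes
  cf0 <- c(0L, cumsum(!mvpa))          # falses in minutes 1..i = cf0[i + 1]
  f_idx <- which(!mvpa)
  last_true <- cummax(ifelse(mvpa, seq_len(n), 0L))
  trues <- which(mvpa)

  # widest qualifying window from each above-threshold start: extend until
  # the interruption budget is spent, then trim trailing interruptions
  budget <- cf0[trues] + tol
  j_raw <- ifelse(budget + 1L <= length(f_idx),
                  f_idx[pmin(budget + 1L, length(f_idx))] - 1L, n)
  j <- last_true[j_raw]
  keep <- (j - trues + 1L) >= defn$min_duration
  i_k <- trues[keep]; j_k <- j[keep]
  if (!length(i_k)) {
    return(tibble(start = integer(), end = integer(), duration = integer()))
  }

  # merge overlapping windows into maximal bouts (starts are increasing and
  # ends non-decreasing; windows adjacent on a true minute cannot occur
  # because the earlier window would have extended over it)
  starts <- i_k[1]; ends <- j_k[1]
  for (m in seq_along(i_k)[-1]) {
    if (i_k[m] <= ends[length(ends)]) {
      ends[length(ends)] <- max(ends[length(ends)], j_k[m])
    } else {
      starts <- c(starts, i_k[m])
      ends <- c(ends, j_k[m])
    }
  }
  tibble(start = starts, end = ends + 1L, duration = ends - starts + 1L)
}

#' Daily MVPA with and without the bout requirement
#'
#' For each subject, calendar day and cut-point scheme: `nonbout_minutes`
#' counts every worn minute at or above the scheme's MET threshold;
#' `bout_minutes` counts only minutes inside detected bouts (so
#' `bout_minutes <= nonbout_minutes` always); `bout_count` is the number of
#' bouts. Non-wear and missing minutes are below threshold by definition
#' and terminate runs.
#'
#' @param records Minute records with `subject_id, timestamp, mets, wear`.
#' @param profiles Profiles tibble (for the per-subject thresholds).
#' @param schemes Scheme names, see [met_schemes()].
#' @param defn A [bout_definition()].
#' @param resting_mets Passed to [met_threshold()].
#' @param tz Time zone of the calendar-day boundary.
#' @return Tibble `subject_id, date, scheme, threshold, nonbout_minutes,
#'   bout_minutes, bout_count` with one row per subject-day-scheme,
#'   including zero rows for days without any MVPA.
#' @export
daily_mvpa <- function(records, profiles, schemes = met_schemes(),
                       defn = bout_definition(), resting_mets = 1,
                       tz = "UTC") {
  assert_columns(records, c("subject_id", "timestamp", "mets", "wear"),
                 "records")
  thresholds <- add_met_thresholds(profiles, schemes, resting_mets)

  base <- records |>
    filter(.data$wear) |>
    mutate(
      date = as.Date(.data$timestamp, tz = tz),
      minute = minute_of_day(.data$timestamp)
    ) |>
    arrange(.data$subject_id, .data$timestamp)
  skeleton <- records |>
    mutate(date = as.Date(.data$timestamp, tz = tz)) |>
    distinct(.data$subject_id, .data$date)

  purrr::map(schemes, function(s) {
    thr <- thresholds |> filter(.data$scheme == s)
    df <- base |>
      inner_join(select(thr, "subject_id", "threshold"), by = "subject_id") |>
      mutate(mvpa = .data$mets >= .data$threshold)
    counted <- if (defn$mode == "strict" || defn$tolerance_minutes == 0L) {
      count_bouts_strict(df, defn)
    } else {
      count_bouts_windowed(df, defn)
    }
    skeleton |>
      left_join(counted, by = c("subject_id", "date")) |>
      left_join(distinct(thr, .data$subject_id, .data$threshold),
                by = "subject_id") |>
      mutate(
        scheme = s,
        nonbout_minutes = dplyr::coalesce(.data$nonbout_minutes, 0L),
        bout_minutes = dplyr::coalesce(.data$bout_minutes, 0L),
        bout_count = dplyr::coalesce(.data$bout_count, 0L)
      ) |>
      select("subject_id", "date", "scheme", "threshold",
             "nonbout_minutes", "bout_minutes", "bout_count")
  }) |>
    bind_rows() |>
    arrange(.data$subject_id, .data$date, .data$scheme)
}

# Fast strict-mode path: maximal runs of consecutive MVPA minutes found
# vectorised over the whole table (a run breaks at any subject/day change,
# any gap in the minute sequence, i.e. missing or non-wear epochs, and any
# below-threshold minute).
count_bouts_strict <- function(df, defn) {
  nonbout <- df |>
    group_by(.data$subject_id, .data$date) |>
    summarise(nonbout_minutes = as.integer(sum(.data$mvpa)), .groups = "drop")

  act <- df |> filter(.data$mvpa)
  if (nrow(act) == 0) {
    return(nonbout |> mutate(bout_minutes = 0L, bout_count = 0L))
  }
  act <- act |>
    mutate(
      new_run = .data$subject_id != lag(.data$subject_id, default = "") |
        .data$date != lag(.data$date, default = as.Date("1900-01-01")) |
        .data$minute != lag(.data$minute, default = -10L) + 1L,
      run_id = cumsum(.data$new_run)
    )
  runs <- act |>
    group_by(.data$subject_id, .data$date, .data$run_id) |>
    summarise(len = dplyr::n(), .groups = "drop")
  bouts <- runs |>
    group_by(.data$subject_id, .data$date) |>
    summarise(
      bout_minutes = as.integer(sum(.data$len[.data$len >= defn$min_duration])),
      bout_count = as.integer(sum(.data$len >= defn$min_duration)),
      .groups = "drop"
    )
  nonbout |>
    left_join(bouts, by = c("subject_id", "date")) |>
    mutate(
      bout_minutes = dplyr::coalesce(.data$bout_minutes, 0L),
      bout_count = dplyr::coalesce(.data$bout_count, 0L)
    )
}

# Tolerant mode: materialize each day as a 1440-minute indicator vector and
# run the windowed detector.
count_bouts_windowed <- function(df, defn) {
  df |>
    group_by(.data$subject_id, .data$date) |>
    summarise(
      {
        v <- rep(FALSE, 1440L)
        v[.data$minute[.data$mvpa] + 1L] <- TRUE
        b <- detect_bouts(v, defn)
        tibble(
          nonbout_minutes = as.integer(sum(v)),
          bout_minutes = as.integer(sum(b$duration)),
          bout_count = nrow(b)
        )
      },
      .groups = "drop"
    )
}

#' Per-subject MVPA summary over valid days
#'
#' Averages the daily bout and non-bout MVPA of [daily_mvpa()] over each
#' subject's valid days only (invalid days and subjects without a valid
#' assessment contribute nothing to cohort statistics). The fold ratio
#' non-bout / bout summarizes how much activity arrives outside
#' qualifying bouts; it is undefined (`NA`) when bout MVPA is zero.
#'
#' @param daily Output of [daily_mvpa()].
#' @param days Day summaries from [summarize_days()] (per subject).
#' @param assessments Output of [is_valid_assessment()] (per subject).
#' @return Tibble `subject_id, scheme, threshold, mvpa_nonbout, mvpa_bout,
#'   bout_count, fold_ratio` restricted to subjects with a valid
#'   assessment; errors if none is valid.
#' @export
summarize_mvpa <- function(daily, days, assessments) {
  assert_columns(assessments, c("subject_id", "valid"), "assessments")
  valid_subjects <- assessments$subject_id[assessments$valid]
  if (length(valid_subjects) == 0) {
    abort("no valid assessments: every subject fails the wear-time criteria")
  }
  valid_days <- days |>
    filter(.data$valid_day, .data$subject_id %in% valid_subjects) |>
    select("subject_id", "date")
  daily |>
    semi_join(valid_days, by = c("subject_id", "date")) |>
    group_by(.data$subject_id, .data$scheme) |>
    summarise(
      threshold = first(.data$threshold),
      mvpa_nonbout = mean(.data$nonbout_minutes),
      mvpa_bout = mean(.data$bout_minutes),
      bout_count = mean(.data$bout_count),
      .groups = "drop"
    ) |>
    mutate(
      fold_ratio = if_else(.data$mvpa_bout > 0,
                           .data$mvpa_nonbout / .data$mvpa_bout, NA_real_)
    )
}
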