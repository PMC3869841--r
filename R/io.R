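#' Describe the on-disk dialect of a minute-epoch trace file
#'
#' Minute-by-minute exports from multisensor armband software are delimited
#' text with one row per recorded epoch. The canonical dialect used by this
#' package is comma-separated with ISO-8601 timestamps and columns
#' `timestamp, mets, wear, sleep`; alternate delimiters and column names from
#' other export configurations can be accommodated here.
#'
#' @param delim Field delimiter (default `","`).
#' @param col_timestamp,col_mets,col_wear,col_sleep Column names in the file.
#' @param tz Time zone used to parse timestamps (default `"UTC"`).
#' @return A list of class `trace_dialect`.
#' @export
#' @examples
#' trace_dialect(delim = ";", col_mets = "METs")
trace_dialect <- function(delim = ",",
                          col_timestamp = "timestamp",
                          col_mets = "mets",
                          col_wear = "wear",
                          col_sleep = "sleep",
                          tz = "UTC") {
  structure(
    list(
      delim = delim, col_timestamp = col_timestamp, col_mets = col_mets,
      col_wear = col_wear, col_sleep = col_sleep, tz = tz
    ),
    class = "trace_dialect"
  )
}

#' Read a minute-epoch activity trace
#'
#' Reads one subject's minute-by-minute trace (timestamp, estimated METs,
#' wear flag, optional sleep flag) from delimited text. Epochs are
#' left-labelled and half-open: the row stamped 10:00 covers the minute
#' \[10:00, 10:01). Missing epochs are preserved as gaps, not imputed;
#' downstream wear accounting treats them as non-wear minutes.
#'
#' @param path File to read.
#' @param dialect A [trace_dialect()] describing delimiter and column names.
#' @return A tibble with columns `timestamp` (POSIXct), `mets` (double),
#'   `wear`, `sleep` (logical), sorted by time. The number of missing
#'   minute epochs between the first and last record is attached as
#'   attribute `n_gap_minutes` and reported via a message.
#' @details Malformed timestamps are a parse error naming the offending
#'   line; duplicated minutes are an integrity error; negative METs are a
#'   validation error. No rows are ever silently dropped.
#' @seealso [write_trace()], [read_subjects()]
#' @export
read_trace <- function(path, dialect = trace_dialect()) {
  if (!file.exists(path)) abort(sprintf("trace file does not exist: %s", path))
  raw <- readr::read_delim(
    path,
    delim = dialect$delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  assert_columns(raw, c(dialect$col_timestamp, dialect$col_mets, dialect$col_wear),
                 "trace file")

  ts <- parse_timestamps(raw[[dialect$col_timestamp]], dialect$tz)
  bad <- which(is.na(ts) | is.na(raw[[dialect$col_timestamp]]))
  if (length(bad)) {
    abort(sprintf(
      "malformed timestamp at data line %d: %s",
      bad[1], raw[[dialect$col_timestamp]][bad[1]]
    ))
  }
  mets <- suppressWarnings(as.numeric(raw[[dialect$col_mets]]))
  if (anyNA(mets)) {
    abort(sprintf("non-numeric METs value at data line %d", which(is.na(mets))[1]))
  }
  if (any(mets < 0)) {
    abort(sprintf("negative METs value at data line %d", which(mets < 0)[1]))
  }
  wear <- parse_flag(raw[[dialect$col_wear]], "wear")
  sleep <- if (dialect$col_sleep %in% names(raw)) {
    parse_flag(raw[[dialect$col_sleep]], "sleep")
  } else {
    rep(FALSE, nrow(raw))
  }

  out <- tibble(timestamp = ts, mets = mets, wear = wear, sleep = sleep) |>
    arrange(.data$timestamp)
  if (anyDuplicated(out$timestamp)) {
    dup <- out$timestamp[duplicated(out$timestamp)][1]
    abort(sprintf("duplicate minute epoch: %s", format(dup, "%Y-%m-%d %H:%M")))
  }
  n_gaps <- 0L
  if (nrow(out) > 1) {
    steps <- as.numeric(diff(out$timestamp), units = "mins")
    if (any(steps < 1)) abort("timestamps are not aligned to whole minutes")
    n_gaps <- as.integer(sum(steps - 1))
  }
  if (n_gaps > 0) {
    inform(sprintf("%d missing minute epoch(s) preserved as gaps", n_gaps))
  }
  attr(out, "n_gap_minutes") <- n_gaps
  out
}

# Try each accepted format in turn; strptime leaves NA where none matches.
parse_timestamps <- function(x, tz) {
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = tz,
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = tz))
  }
  out
}

parse_flag <- function(x, what) {
  v <- tolower(trimws(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "")] <- FALSE
  out[is.na(x)] <- FALSE
  if (anyNA(out)) {
    abort(sprintf("unrecognized %s flag at data line %d: %s",
                  what, which(is.na(out))[1], x[which(is.na(out))[1]]))
  }
  as.logical(out)
}

#' Write a minute-epoch activity trace
#'
#' Deterministic inverse of [read_trace()]: fixed column order
#' (timestamp, mets, wear, sleep), ISO-8601 timestamps, shortest
#' round-trip numeric formatting, so `read_trace(write_trace(x))`
#' reproduces every data field exactly.
#'
#' @param trace A tibble as returned by [read_trace()] (a `subject_id`
#'   column, if present, is dropped: trace files hold one subject).
#' @param path File to write.
#' @param dialect A [trace_dialect()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, dialect = trace_dialect()) {
  assert_columns(trace, c("timestamp", "mets", "wear"), "trace")
  sleep <- if ("sleep" %in% names(trace)) trace$sleep else rep(FALSE, nrow(trace))
  out <- tibble(
    timestamp = format(trace$timestamp, "%Y-%m-%dT%H:%M:%S", tz = dialect$tz),
    mets = trace$mets,
    wear = trace$wear,
    sleep = sleep
  )
  names(out) <- c(dialect$col_timestamp, dialect$col_mets,
                  dialect$col_wear, dialect$col_sleep)
  readr::write_delim(out, path, delim = dialect$delim, progress = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' One row per subject with the demographics and exercise-capacity fields
#' needed by the relative MET cut-points and the resting-energy-expenditure
#' prediction equations. `sex`, `group` and `wear_protocol` tokens are
#' normalized case-insensitively.
#'
#' @param path Delimited text file with columns `subject_id, age, sex,
#'   height_cm, weight_kg, mets_max, group, wear_protocol`.
#' @param delim Field delimiter (default `","`).
#' @return A tibble, one profile per input row, in file order.
#' @export
read_subjects <- function(path, delim = ",") {
  if (!file.exists(path)) abort(sprintf("subject file does not exist: %s", path))
  raw <- readr::read_delim(path, delim = delim, progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  assert_columns(raw, c("subject_id", "age", "sex", "height_cm", "weight_kg",
                        "mets_max", "group", "wear_protocol"), "subject file")
  out <- tibble(
    subject_id = raw$subject_id,
    age = as.integer(raw$age),
    sex = normalize_token(raw$sex, c("male", "female"), "sex",
                          aliases = c(m = "male", f = "female")),
    height_cm = as.numeric(raw$height_cm),
    weight_kg = as.numeric(raw$weight_kg),
    mets_max = as.numeric(raw$mets_max),
    group = normalize_token(raw$group, c("healthy", "copd"), "group"),
    wear_protocol = normalize_token(raw$wear_protocol,
                                    c("full_day", "waking_hours"),
                                    "wear_protocol")
  )
  validate_profiles(out)
  out
}

normalize_token <- function(x, allowed, what, aliases = character()) {
  v <- tolower(trimws(x))
  if (length(aliases)) {
    hit <- v %in% names(aliases)
    v[hit] <- unname(aliases[v[hit]])
  }
  bad <- which(!v %in% allowed)
  if (length(bad)) {
    abort(sprintf("unknown %s value at row %d: %s (allowed: %s)",
                  what, bad[1], x[bad[1]], paste(allowed, collapse = ", ")))
  }
  v
}

validate_profiles <- function(profiles) {
  with(profiles, {
    if (anyNA(age) || any(age <= 0)) abort("age must be a positive integer")
    if (anyNA(height_cm) || any(height_cm <= 0)) abort("height_cm must be > 0")
    if (anyNA(weight_kg) || any(weight_kg <= 0)) abort("weight_kg must be > 0")
    if (anyNA(mets_max) || any(mets_max < 1)) abort("mets_max must be >= 1")
  })
  if (anyDuplicated(profiles$subject_id)) abort("duplicate subject_id")
  invisible(profiles)
}

#' Write a subject metadata table
#'
#' @param profiles A profiles tibble (see [read_subjects()]).
#' @param path File to write.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(profiles, path, delim = ",") {
  cols <- c("subject_id", "age", "sex", "height_cm", "weight_kg",
            "mets_max", "group", "wear_protocol")
  assert_columns(profiles, cols, "profiles")
  readr::write_delim(profiles[cols], path, delim = delim, progress = FALSE)
  invisible(path)
}
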