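# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no data files.

# Build minute records from a METs vector starting at `start_min` minutes
# after local midnight of `date`.
mk_records <- function(mets, date = "2024-03-04", start_min = 0,
                       wear = TRUE, sleep = FALSE, subject_id = NULL) {
  n <- length(mets)
  out <- tibble::tibble(
    timestamp = as.POSIXct(as.Date(date), tz = "UTC") +
      60 * (start_min + seq_len(n) - 1L),
    mets = mets,
    wear = rep_len(wear, n),
    sleep = rep_len(sleep, n)
  )
  if (!is.null(subject_id)) {
    out <- dplyr::mutate(out, subject_id = subject_id, .before = 1)
  }
  out
}

mk_profile <- function(subject_id = "S1", age = 62L, sex = "male",
                       height_cm = 175, weight_kg = 70, mets_max = 8.3,
                       group = "healthy", wear_protocol = "full_day") {
  tibble::tibble(
    subject_id = subject_id, age = as.integer(age), sex = sex,
    height_cm = height_cm, weight_kg = weight_kg, mets_max = mets_max,
    group = group, wear_protocol = wear_protocol
  )
}

# Day summaries for constructed calendars: `wear_minutes` named by date.
mk_days <- function(wear_minutes, dates) {
  dates <- as.Date(dates)
  tibble::tibble(
    date = dates,
    wear_minutes = as.integer(wear_minutes),
    is_weekend = as.POSIXlt(dates)$wday %in% c(0L, 6L),
    valid_day = wear_minutes >= 720
  )
}

# O(n^2) all-windows brute-force bout oracle. Enumerates every qualifying
# window (starts and ends on an above-threshold minute, below-threshold
# count <= tol, length >= min_dur), marks every minute covered by at least
# one such window, and reports the connected components of the covered set.
brute_force_bouts <- function(x, min_dur = 10, tol = 0) {
  n <- length(x)
  idx <- which(x)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          duration = integer())
  if (!length(idx)) return(empty)
  cf <- c(0L, cumsum(!x))
  pairs <- expand.grid(i = idx, j = idx)
  pairs <- pairs[pairs$j - pairs$i + 1L >= min_dur, , drop = FALSE]
  if (nrow(pairs)) {
    falses <- cf[pairs$j + 1L] - cf[pairs$i]
    pairs <- pairs[falses <= tol, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  covered <- rep(FALSE, n)
  for (r in seq_len(nrow(pairs))) covered[pairs$i[r]:pairs$j[r]] <- TRUE
  runs <- rle(covered)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  tibble::tibble(start = starts[keep], end = ends[keep] + 1L,
                 duration = runs$lengths[keep])
}

# Mann-Whitney pair-counting AUC estimator (ties counted one half).
auc_mann_whitney <- function(metric, reference) {
  pos <- metric[reference]
  neg <- metric[!reference]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Small cohort used by several property tests (kept at module scope so it
# is generated once per test file that needs it).
small_cohort <- function(n_healthy = 20, n_copd = 20, seed = 424242) {
  generate_cohort(cohort_spec(n_healthy = n_healthy, n_copd = n_copd,
                              seed = seed))
}
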