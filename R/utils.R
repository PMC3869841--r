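# Shared internal helpers.

# Truncated normal via inverse-CDF; exact, vectorised, no rejection loop.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

# Wilson score interval for a binomial proportion (no continuity correction).
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

# Linear-interpolation quantiles (R type 7), the convention used for all
# median [IQR] summaries in report tables.
med_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7, na.rm = TRUE)
  tibble(median = q[2], q1 = q[1], q3 = q[3])
}

fmt_med_iqr <- function(median, q1, q3, digits = 0) {
  sprintf(
    "%s [%s-%s]",
    formatC(round(median, digits), format = "f", digits = digits),
    formatC(round(q1, digits), format = "f", digits = digits),
    formatC(round(q3, digits), format = "f", digits = digits)
  )
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

is_weekend_date <- function(date) {
  # POSIXlt wday: 0 = Sunday, 6 = Saturday
  wd <- as.POSIXlt(date)$wday
  wd == 0L | wd == 6L
}

minute_of_day <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  lt$hour * 60L + lt$min
}
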