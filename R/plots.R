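#' Distribution of daily MVPA by group, scheme and analysis type
#'
#' Box plots of per-subject mean daily MVPA, bout versus non-bout, on a
#' square-root scale (the cohort distributions are right-skewed).
#'
#' @param summaries Output of [summarize_mvpa()], with a `group` column
#'   joined on.
#' @return A ggplot object.
#' @export
plot_mvpa_distribution <- function(summaries) {
  assert_columns(summaries, c("scheme", "mvpa_nonbout", "mvpa_bout"),
                 "summaries")
  if (!"group" %in% names(summaries)) summaries$group <- "all"
  df <- summaries |>
    tidyr::pivot_longer(c("mvpa_nonbout", "mvpa_bout"),
                        names_to = "analysis", values_to = "minutes") |>
    mutate(analysis = if_else(.data$analysis == "mvpa_bout",
                              "bouts", "non-bouts"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scheme, y = .data$minutes,
                                   fill = .data$analysis)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(x = "Cut-point scheme", y = "MVPA (min/day)",
                  fill = "Analysis") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' One subject-day MET trace
#'
#' Minute-level MET profile for a single subject and day, with the MVPA
#' threshold line and detected bouts shaded.
#'
#' @param records Minute records (one subject).
#' @param date Calendar day to plot.
#' @param threshold MET threshold drawn as a reference line (default 3).
#' @param defn A [bout_definition()] for the shading.
#' @param tz Time zone of the calendar-day boundary.
#' @return A ggplot object.
#' @export
plot_day_trace <- function(records, date, threshold = 3,
                           defn = bout_definition(), tz = "UTC") {
  assert_columns(records, c("timestamp", "mets", "wear"), "records")
  date <- as.Date(date)
  day <- records |>
    filter(as.Date(.data$timestamp, tz = tz) == date) |>
    mutate(minute = minute_of_day(.data$timestamp))
  if (nrow(day) == 0) abort("no records on that date")
  v <- rep(FALSE, 1440L)
  v[day$minute[day$wear & day$mets >= threshold] + 1L] <- TRUE
  bouts <- detect_bouts(v, defn)

  p <- ggplot2::ggplot(day, ggplot2::aes(x = .data$minute / 60,
                                         y = .data$mets)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Hour of day", y = "METs",
                  title = format(date, "%A %Y-%m-%d"))
  if (nrow(bouts)) {
    p <- p + ggplot2::geom_rect(
      data = bouts,
      ggplot2::aes(xmin = (.data$start - 1) / 60, xmax = (.data$end - 1) / 60,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "steelblue"
    )
  }
  p
}
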