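#' Define an active/inactive classification target
#'
#' A target names a per-subject summary metric and the inclusive threshold
#' at or above which a subject is classified active. The guideline targets
#' used throughout are 30 min/day of MVPA in bouts (`target_mvpa_bout()`),
#' a physical activity level of 1.7 (`target_pal()`), and a non-bout MVPA
#' cut-point such as the 80 min/day equivalent (`target_mvpa_nonbout()`).
#'
#' @param name Label for the target.
#' @param metric Column of the per-subject summary to threshold.
#' @param threshold Inclusive threshold (> 0).
#' @return A list of class `acti_target`.
#' @export
activity_target <- function(name, metric, threshold) {
  if (threshold <= 0) abort("threshold must be > 0")
  structure(list(name = name, metric = metric, threshold = threshold),
            class = "acti_target")
}

#' @rdname activity_target
#' @param minutes,pal Threshold values for the convenience constructors.
#' @export
target_mvpa_bout <- function(minutes = 30) {
  activity_target(sprintf("bout_%g", minutes), "mvpa_bout", minutes)
}

#' @rdname activity_target
#' @export
target_mvpa_nonbout <- function(minutes = 80) {
  activity_target(sprintf("nonbout_%g", minutes), "mvpa_nonbout", minutes)
}

#' @rdname activity_target
#' @export
target_pal <- function(pal = 1.7) {
  activity_target(sprintf("pal_%g", pal), "pal", pal)
}

#' Classify subjects as active under a target
#'
#' @param data Per-subject summary tibble containing the target's metric
#'   column (e.g. the output of [summarize_mvpa()] or
#'   [summarize_energy()]).
#' @param target An [activity_target()].
#' @return Logical vector, `TRUE` = active (metric >= threshold).
#' @export
#' @examples
#' s <- tibble::tibble(mvpa_bout = c(30, 29.9))
#' classify_active(s, target_mvpa_bout())  # TRUE FALSE
classify_active <- function(data, target) {
  stopifnot(inherits(target, "acti_target"))
  if (!target$metric %in% names(data)) {
    abort(sprintf("metric column '%s' is missing from the summary",
                  target$metric))
  }
  data[[target$metric]] >= target$threshold
}

#' Days-per-week activity rule
#'
#' Optional weekly reading of the guideline frequency component: a subject
#' is active when at least `min_days` of their valid days individually
#' meet the target.
#'
#' @param daily Per-day tibble with `subject_id` and the target's metric
#'   column (e.g. [daily_mvpa()] output with `bout_minutes` renamed, or
#'   computed day metrics).
#' @param target An [activity_target()].
#' @param min_days Minimum qualifying days (default 5).
#' @return Tibble `subject_id, days_meeting, active`.
#' @export
classify_weekly <- function(daily, target, min_days = 5) {
  stopifnot(inherits(target, "acti_target"))
  assert_columns(daily, c("subject_id", target$metric), "daily summary")
  daily |>
    group_by(.data$subject_id) |>
    summarise(
      days_meeting = sum(.data[[target$metric]] >= target$threshold),
      .groups = "drop"
    ) |>
    mutate(active = .data$days_meeting >= min_days)
}

#' Positive likelihood ratio from sensitivity and specificity
#'
#' `LR+ = sensitivity / (1 - specificity)`: how many times more likely a
#' positive index result is in subjects who meet the reference criterion
#' than in those who do not.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return The positive likelihood ratio (`Inf` when specificity is 1).
#' @export
#' @examples
#' lr_positive(0.86, 0.83)  # 5.06
#' lr_positive(0.98, 0.58)  # 2.33
lr_positive <- function(sensitivity, specificity) {
  sensitivity / (1 - specificity)
}

#' Diagnostic accuracy of one activity target against another
#'
#' Cross-tabulates index-target labels against reference-target labels
#' and reports sensitivity, specificity, false-positive rate and the
#' positive likelihood ratio. Confidence intervals use the Wilson score
#' method for the proportions and the Simel log method for the likelihood
#' ratio: `exp(log(LR) +- z * sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)))`.
#' With zero false positives the likelihood ratio is infinite and is
#' reported with a one-sided interval (lower bound from counts with 0.5
#' added to each cell) and a warning.
#'
#' @param index Logical vector: active under the candidate target.
#' @param reference Logical vector: active under the reference target
#'   (must contain both classes).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `acti_diagnostic` with fields `tp, fp, fn,
#'   tn, n, sensitivity, specificity, fpr, lr_pos` and their confidence
#'   intervals. [tidy()] returns the statistics as a tibble, [glance()] a
#'   one-row summary.
#' @export
diagnostic_accuracy <- function(index, reference, conf_level = 0.95) {
  if (length(index) != length(reference)) {
    abort("index and reference labels must have equal length")
  }
  keep <- !(is.na(index) | is.na(reference))
  index <- index[keep]; reference <- reference[keep]
  if (!any(reference) || all(reference)) {
    abort("reference labels are degenerate: both classes are required")
  }
  tp <- sum(index & reference)
  fp <- sum(index & !reference)
  fn <- sum(!index & reference)
  tn <- sum(!index & !reference)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  z <- qnorm(1 - (1 - conf_level) / 2)

  if (fp == 0) {
    warn("zero false positives: positive likelihood ratio is infinite; reporting a one-sided interval")
    lr <- Inf
    # continuity-corrected lower bound
    tp2 <- tp + 0.5; fn2 <- fn + 0.5; fp2 <- 0.5; tn2 <- tn + 0.5
    lr_cc <- (tp2 / (tp2 + fn2)) / (fp2 / (fp2 + tn2))
    se <- sqrt(1 / tp2 - 1 / (tp2 + fn2) + 1 / fp2 - 1 / (fp2 + tn2))
    lr_ci <- c(exp(log(lr_cc) - z * se), Inf)
  } else {
    lr <- sens / (1 - spec)
    se <- sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
    lr_ci <- exp(log(lr) + c(-1, 1) * z * se)
  }

  structure(
    list(
      tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn,
      sensitivity = sens,
      sensitivity_ci = wilson_ci(tp, tp + fn, conf_level),
      specificity = spec,
      specificity_ci = wilson_ci(tn, tn + fp, conf_level),
      fpr = 1 - spec,
      lr_pos = lr, lr_pos_ci = lr_ci,
      conf_level = conf_level
    ),
    class = "acti_diagnostic"
  )
}

#' @export
print.acti_diagnostic <- function(x, ...) {
  cat("<diagnostic accuracy>\n")
  cat(sprintf("  2x2: tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  cat(sprintf("  sensitivity %.1f%% [%.1f-%.1f]   specificity %.1f%% [%.1f-%.1f]\n",
              100 * x$sensitivity, 100 * x$sensitivity_ci[1],
              100 * x$sensitivity_ci[2],
              100 * x$specificity, 100 * x$specificity_ci[1],
              100 * x$specificity_ci[2]))
  cat(sprintf("  LR+ %.2f [%.2f-%.2f]   false-positive rate %.1f%%\n",
              x$lr_pos, x$lr_pos_ci[1], x$lr_pos_ci[2], 100 * x$fpr))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.acti_diagnostic <- function(x, ...) {
  tibble(
    term = c("sensitivity", "specificity", "fpr", "lr_pos"),
    estimate = c(x$sensitivity, x$specificity, x$fpr, x$lr_pos),
    conf.low = c(x$sensitivity_ci[1], x$specificity_ci[1], NA, x$lr_pos_ci[1]),
    conf.high = c(x$sensitivity_ci[2], x$specificity_ci[2], NA, x$lr_pos_ci[2])
  )
}

#' @exportS3Method generics::glance
glance.acti_diagnostic <- function(x, ...) {
  tibble(
    n = x$n, tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
    sensitivity = x$sensitivity, specificity = x$specificity,
    fpr = x$fpr, lr_pos = x$lr_pos
  )
}
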