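#' Random split-sample partition
#'
#' Partitions subjects uniformly at random (without replacement) into a
#' calibration set used to derive cut-points and a held-out validation
#' set, in the given ratio. The calibration size is the nearest integer
#' to `n * ratio / (ratio + 1)`, ties going to calibration: 110 subjects
#' at 2:1 give 73 calibration and 37 validation.
#'
#' @param subject_ids Character vector of ids (>= 3).
#' @param ratio Calibration:validation ratio expressed as a single number
#'   (default 2, i.e. 2:1).
#' @param seed Optional integer seed.
#' @return Tibble `subject_id, sample` with `sample` in
#'   `c("calibration", "validation")`.
#' @export
split_sample <- function(subject_ids, ratio = 2, seed = NULL) {
  n <- length(subject_ids)
  if (n < 3) abort("split_sample() needs at least 3 subjects")
  if (anyDuplicated(subject_ids)) abort("subject_ids must be unique")
  n_cal <- as.integer(floor(n * ratio / (ratio + 1) + 0.5))
  n_cal <- max(1L, min(n - 1L, n_cal))
  draw <- function() sample(subject_ids, n_cal)
  cal <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(
    subject_id = subject_ids,
    sample = if_else(subject_ids %in% cal, "calibration", "validation")
  )
}

#' ROC analysis of a non-bout MVPA metric against a reference label
#'
#' Builds the ROC curve over all distinct observed metric values (plus an
#' upper sentinel), classifying active at metric >= threshold. The area
#' under the curve is computed by the trapezoidal rule (equal to the
#' Mann-Whitney pair-counting estimator with ties counted one half), with
#' a DeLong-type variance for its confidence interval. The optimal
#' cut-point maximizes Youden's J = sensitivity + specificity - 1 (the
#' threshold "at which sensitivity and specificity are both maximized"),
#' ties broken toward the larger, more specific, threshold; it is
#' reported in whole minutes.
#'
#' @param metric Numeric per-subject values (e.g. non-bout MVPA min/day).
#' @param reference Logical per-subject reference labels (both classes
#'   required), e.g. from [classify_active()] with [target_mvpa_bout()].
#' @param conf_level Confidence level for the AUC interval.
#' @return An object of class `acti_roc`: `curve` (tibble `threshold,
#'   sens, spec`), `auc`, `auc_ci`, `auc_grade` (excellent >= 0.90 / good
#'   0.80-0.89 / fair 0.70-0.79 / poor < 0.70), `optimal_threshold`
#'   (whole minutes; `optimal_threshold_raw` before rounding),
#'   `optimal_sens`, `optimal_spec`, `youden`. Methods:
#'   [tidy()] (the curve), [glance()] (one-row summary),
#'   [ggplot2::autoplot()].
#' @export
roc_curve <- function(metric, reference, conf_level = 0.95) {
  if (length(metric) != length(reference)) {
    abort("metric and reference must have equal length")
  }
  keep <- !(is.na(metric) | is.na(reference))
  metric <- metric[keep]; reference <- as.logical(reference[keep])
  if (!any(reference) || all(reference)) {
    abort("reference labels are degenerate: both classes are required")
  }
  thresholds <- c(sort(unique(metric)), Inf)
  pos <- metric[reference]
  neg <- metric[!reference]
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))

  # trapezoid over (fpr, tpr), ordered by increasing fpr
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  xs <- c(0, fpr[ord], 1); ys <- c(0, sens[ord], 1)
  # the curve is traversed from (1,1) (threshold -Inf) to (0,0); after
  # ordering it runs (0,0) -> (1,1)
  auc <- sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)

  auc_ci <- delong_ci(pos, neg, auc, conf_level)

  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[length(best)]                 # ties -> larger threshold
  thr_raw <- thresholds[best]
  if (!is.finite(thr_raw)) thr_raw <- max(metric) + 1
  thr <- round(thr_raw)
  # report performance at the rounded (whole-minute) cut-point
  opt_sens <- mean(pos >= thr)
  opt_spec <- mean(neg < thr)

  structure(
    list(
      curve = tibble(threshold = thresholds, sens = sens, spec = spec),
      n_pos = length(pos), n_neg = length(neg),
      auc = auc, auc_ci = auc_ci, auc_grade = auc_grade(auc),
      optimal_threshold = thr, optimal_threshold_raw = thr_raw,
      optimal_sens = opt_sens,
      optimal_spec = opt_spec, youden = opt_sens + opt_spec - 1,
      conf_level = conf_level
    ),
    class = "acti_roc"
  )
}

# DeLong variance of the Mann-Whitney AUC via placement values; falls back
# to a stratified bootstrap when either class has a single observation.
delong_ci <- function(pos, neg, auc, conf_level) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  m <- length(pos); n <- length(neg)
  psi <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  if (m >= 2 && n >= 2) {
    v10 <- rowMeans(psi)
    v01 <- colMeans(psi)
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  } else {
    boot <- replicate(500, {
      bp <- sample(pos, m, replace = TRUE)
      bn <- sample(neg, n, replace = TRUE)
      mean(outer(bp, bn, function(x, y) (x > y) + 0.5 * (x == y)))
    })
    se <- sd(boot)
  }
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' Qualitative AUC grade
#'
#' @param auc Area under the ROC curve.
#' @return `"excellent"` (>= 0.90), `"good"` (0.80-0.89), `"fair"`
#'   (0.70-0.79) or `"poor"` (< 0.70).
#' @export
auc_grade <- function(auc) {
  case_when(
    auc >= 0.90 ~ "excellent",
    auc >= 0.80 ~ "good",
    auc >= 0.70 ~ "fair",
    TRUE ~ "poor"
  )
}

#' @export
print.acti_roc <- function(x, ...) {
  cat(sprintf("<ROC> AUC %.3f [%.3f-%.3f] (%s); optimal cut-point %g (sens %.2f, spec %.2f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$auc_grade,
              x$optimal_threshold, x$optimal_sens, x$optimal_spec))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.acti_roc <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.acti_roc <- function(x, ...) {
  tibble(
    auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
    auc_grade = x$auc_grade, optimal_threshold = x$optimal_threshold,
    optimal_sens = x$optimal_sens, optimal_spec = x$optimal_spec,
    n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @exportS3Method ggplot2::autoplot
#' @importFrom ggplot2 autoplot
autoplot.acti_roc <- function(object, ...) {
  df <- object$curve |> mutate(fpr = 1 - .data$spec)
  opt <- tibble(
    fpr = 1 - object$optimal_spec, sens = object$optimal_sens,
    label = sprintf("cut-point %g", object$optimal_threshold)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sens)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(data = opt, colour = "red") +
    ggplot2::geom_text(data = opt, ggplot2::aes(label = .data$label),
                       hjust = -0.1, vjust = 1.5, size = 3) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC: AUC %.2f [%.2f-%.2f]",
                      object$auc, object$auc_ci[1], object$auc_ci[2])
    ) +
    ggplot2::coord_equal()
}

#' Split-sample calibration and validation of a non-bout cut-point
#'
#' Randomly splits the cohort (typically the healthy group), fits one ROC
#' per cut-point scheme on the calibration half -- index metric: that
#' scheme's non-bout MVPA; reference: >= `reference_minutes` of bout MVPA
#' under the same scheme -- selects the scheme with the highest AUC,
#' freezes its optimal cut-point, and recomputes sensitivity, specificity
#' and the positive likelihood ratio on the held-out half at the frozen
#' cut-point. The validation half never influences the cut-point.
#'
#' @param summaries Per-subject MVPA summaries from [summarize_mvpa()]
#'   (columns `subject_id, scheme, mvpa_nonbout, mvpa_bout`).
#' @param reference_minutes Bout-MVPA reference criterion (default 30
#'   min/day).
#' @param ratio,seed Passed to [split_sample()].
#' @param schemes Schemes to calibrate (default: all present).
#' @param conf_level Confidence level.
#' @return An object of class `acti_calibration`: `split`, per-scheme
#'   `calibration` table (cut-point, sens, spec, AUC with CIs), `rocs`
#'   (list of `acti_roc`), `best_scheme`, `threshold`, and `validation`
#'   (an `acti_diagnostic` on the held-out half). [tidy()] returns the
#'   calibration table; [glance()] the selected scheme's row plus
#'   validation statistics.
#' @export
calibrate_and_validate <- function(summaries, reference_minutes = 30,
                                   ratio = 2, seed = NULL, schemes = NULL,
                                   conf_level = 0.95) {
  assert_columns(summaries, c("subject_id", "scheme", "mvpa_nonbout",
                              "mvpa_bout"), "summaries")
  schemes <- schemes %||% unique(summaries$scheme)
  ids <- unique(summaries$subject_id)
  split <- split_sample(ids, ratio, seed)
  cal_ids <- split$subject_id[split$sample == "calibration"]
  val_ids <- split$subject_id[split$sample == "validation"]

  rocs <- purrr::map(schemes, function(s) {
    d <- summaries |>
      filter(.data$scheme == s, .data$subject_id %in% cal_ids)
    ref <- d$mvpa_bout >= reference_minutes
    if (!any(ref) || all(ref)) {
      abort(sprintf(
        "scheme %s: only one reference class in the calibration half; re-seed the split or enlarge the cohort", s))
    }
    roc_curve(d$mvpa_nonbout, ref, conf_level)
  })
  names(rocs) <- schemes

  calibration <- purrr::imap(rocs, function(r, s) {
    glance(r) |> mutate(scheme = s, .before = 1)
  }) |> bind_rows()

  best_scheme <- calibration$scheme[which.max(calibration$auc)]
  threshold <- rocs[[best_scheme]]$optimal_threshold

  val <- summaries |>
    filter(.data$scheme == best_scheme, .data$subject_id %in% val_ids)
  ref <- val$mvpa_bout >= reference_minutes
  if (!any(ref) || all(ref)) {
    abort("only one reference class in the validation half; re-seed the split or enlarge the cohort")
  }
  validation <- diagnostic_accuracy(val$mvpa_nonbout >= threshold, ref,
                                    conf_level)

  structure(
    list(split = split, calibration = calibration, rocs = rocs,
         best_scheme = best_scheme, threshold = threshold,
         reference_minutes = reference_minutes, validation = validation),
    class = "acti_calibration"
  )
}

#' @export
print.acti_calibration <- function(x, ...) {
  cat(sprintf("<calibration> %d calibration / %d validation subjects\n",
              sum(x$split$sample == "calibration"),
              sum(x$split$sample == "validation")))
  print(x$calibration)
  cat(sprintf("selected: %s, non-bout cut-point %g min/day (reference: %g min bout MVPA)\n",
              x$best_scheme, x$threshold, x$reference_minutes))
  cat("held-out validation:\n")
  print(x$validation)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.acti_calibration <- function(x, ...) x$calibration

#' @exportS3Method generics::glance
glance.acti_calibration <- function(x, ...) {
  v <- glance(x$validation)
  tibble(
    best_scheme = x$best_scheme, threshold = x$threshold,
    auc = x$calibration$auc[x$calibration$scheme == x$best_scheme],
    val_sensitivity = v$sensitivity, val_specificity = v$specificity,
    val_lr_pos = v$lr_pos, n_validation = v$n
  )
}

#' Validate a frozen cut-point in an external sample
#'
#' Applies an already-derived non-bout cut-point to another cohort (e.g.
#' the COPD group) against the same bout-MVPA reference criterion.
#'
#' @inheritParams calibrate_and_validate
#' @param threshold Frozen non-bout cut-point (min/day).
#' @param scheme Scheme whose summaries to use.
#' @return An `acti_diagnostic`.
#' @export
validate_cutpoint <- function(summaries, threshold, reference_minutes = 30,
                              scheme = "acsm_aha", conf_level = 0.95) {
  d <- summaries |> filter(.data$scheme == !!scheme)
  if (nrow(d) == 0) abort(sprintf("no summaries for scheme %s", scheme))
  diagnostic_accuracy(d$mvpa_nonbout >= threshold,
                      d$mvpa_bout >= reference_minutes, conf_level)
}

#' Regression-based equivalence between two activity metrics
#'
#' Ordinary least squares of one per-subject metric on another, reporting
#' the predicted response at a given predictor value with both a
#' confidence interval (for the mean response) and a prediction interval
#' (for a new subject). Used to express, e.g., how many non-bout MVPA
#' minutes correspond to 30 min of bout MVPA, or how many MVPA minutes
#' correspond to a PAL of 1.7.
#'
#' @param data Per-subject tibble.
#' @param predictor,response Unquoted column names.
#' @param at Predictor value at which to predict.
#' @param conf_level Interval level (default 0.95).
#' @return One-row tibble `at, estimate, conf.low, conf.high, pred.low,
#'   pred.high, intercept, slope, r.squared, n`, with the fitted `lm`
#'   attached as attribute `model`.
#' @export
#' @examples
#' d <- tibble::tibble(bout = c(10, 20, 30, 40), nonbout = c(30, 55, 85, 100))
#' regression_equivalence(d, bout, nonbout, at = 30)
regression_equivalence <- function(data, predictor, response, at,
                                   conf_level = 0.95) {
  x <- dplyr::pull(data, {{ predictor }})
  y <- dplyr::pull(data, {{ response }})
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("regression_equivalence() needs n >= 3")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    abort("predictor has zero variance")
  }
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  nd <- data.frame(x = at)
  ci <- suppressWarnings(
    predict(fit, nd, interval = "confidence", level = conf_level))
  pi <- suppressWarnings(
    predict(fit, nd, interval = "prediction", level = conf_level))
  out <- tibble(
    at = at,
    estimate = unname(ci[1, "fit"]),
    conf.low = unname(ci[1, "lwr"]), conf.high = unname(ci[1, "upr"]),
    pred.low = unname(pi[1, "lwr"]), pred.high = unname(pi[1, "upr"]),
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    r.squared = suppressWarnings(summary(fit)$r.squared),
    n = length(x)
  )
  attr(out, "model") <- fit
  out
}
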