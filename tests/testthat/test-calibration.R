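test_that("split sample hits the published 2:1 sizes", {
  ids <- sprintf("S%03d", 1:110)
  sp <- split_sample(ids, ratio = 2, seed = 1)
  expect_equal(sum(sp$sample == "calibration"), 73L)
  expect_equal(sum(sp$sample == "validation"), 37L)
  expect_setequal(sp$subject_id, ids)

  sp3 <- split_sample(c("a", "b", "c"), seed = 1)
  expect_equal(sum(sp3$sample == "calibration"), 2L)

  expect_equal(sum(split_sample(sprintf("s%d", 1:9), seed = 2)$sample ==
                     "calibration"), 6L)
  expect_error(split_sample(c("a", "b")), "at least 3")
  expect_equal(split_sample(ids, seed = 7), split_sample(ids, seed = 7))
  expect_false(identical(split_sample(ids, seed = 7),
                         split_sample(ids, seed = 8)))
})

test_that("ROC handles separable and chance data correctly", {
  # perfectly separated
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$optimal_sens, 1)
  expect_equal(r$optimal_spec, 1)

  # labels independent of the metric: AUC near 1/2
  set.seed(17)
  r2 <- roc_curve(runif(2000), runif(2000) < 0.5)
  expect_lt(abs(r2$auc - 0.5), 0.05)

  expect_error(roc_curve(1:5, rep(TRUE, 5)), "degenerate")
})

test_that("trapezoidal AUC equals the Mann-Whitney estimator", {
  set.seed(19)
  for (k in 1:200) {
    n <- sample(8:40, 1)
    x <- sample(0:30, n, replace = TRUE)      # heavy ties on purpose
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    r <- roc_curve(x, y)
    expect_equal(r$auc, auc_mann_whitney(x, y), tolerance = 1e-12)
  }
})

test_that("AUC and DeLong interval agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (k in 1:30) {
    n <- sample(20:60, 1)
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    x <- rnorm(n, mean = ifelse(y, 1, 0))
    r <- roc_curve(x, y)
    pr <- pROC::roc(response = y, predictor = x, direction = "<",
                    quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc_ci, c(max(0, ci[1]), min(1, ci[3])),
                 tolerance = 1e-6)
  }
})

test_that("ROC is invariant under strictly increasing transforms", {
  set.seed(29)
  for (k in 1:20) {
    n <- 40
    y <- runif(n) < 0.5
    if (!any(y) || all(y)) next
    x <- rgamma(n, 3, 0.05) + ifelse(y, 40, 0)
    g <- function(v) exp(v / 50)
    r1 <- roc_curve(x, y)
    r2 <- roc_curve(g(x), y)
    expect_equal(r1$auc, r2$auc, tolerance = 1e-12)
    # the selected cut-point classifies the same subjects
    expect_equal(x >= r1$optimal_threshold_raw,
                 g(x) >= r2$optimal_threshold_raw)
  }
})

test_that("Youden ties break toward the larger threshold", {
  # J = 0.5 at both 10 and 20; the more specific cut-point wins
  r <- roc_curve(c(5, 15, 10, 20), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$optimal_threshold, 20)
})

test_that("a deterministic 2.5x relationship recovers its exact cut-point", {
  bout <- c(10, 20, 25, 28, 30, 35, 40, 50)
  s <- tibble::tibble(
    subject_id = sprintf("S%d", seq_along(bout)),
    scheme = "acsm_aha",
    mvpa_bout = bout,
    mvpa_nonbout = 2.5 * bout
  )
  r <- roc_curve(s$mvpa_nonbout, s$mvpa_bout >= 30)
  expect_equal(r$optimal_threshold, 75)
  expect_equal(r$optimal_sens, 1)
  expect_equal(r$optimal_spec, 1)
})

test_that("calibration freezes the cut-point before touching the holdout", {
  set.seed(31)
  n <- 120
  s_scale <- exp(rnorm(n, 0, 0.5))
  summ <- tibble::tibble(
    subject_id = sprintf("S%03d", 1:n),
    scheme = "acsm_aha",
    mvpa_bout = 39 * s_scale + rnorm(n, 0, 6),
    mvpa_nonbout = 106 * s_scale + rnorm(n, 0, 8)
  )
  summ$mvpa_bout <- pmax(0, summ$mvpa_bout)
  cal <- calibrate_and_validate(summ, seed = 7)

  # self-consistency: re-validating on the calibration half reproduces the
  # calibration operating point
  cal_ids <- cal$split$subject_id[cal$split$sample == "calibration"]
  d_cal <- dplyr::filter(summ, .data$subject_id %in% cal_ids)
  self <- diagnostic_accuracy(d_cal$mvpa_nonbout >= cal$threshold,
                              d_cal$mvpa_bout >= 30)
  roc <- cal$rocs[["acsm_aha"]]
  expect_equal(self$sensitivity, roc$optimal_sens)
  expect_equal(self$specificity, roc$optimal_spec)

  # leakage: shuffling the holdout's reference labels changes validation
  # statistics but can never move the frozen threshold
  val_ids <- cal$split$subject_id[cal$split$sample == "validation"]
  shuffled <- summ
  vi <- shuffled$subject_id %in% val_ids
  shuffled$mvpa_bout[vi] <- withr::with_seed(99, sample(shuffled$mvpa_bout[vi]))
  cal2 <- calibrate_and_validate(shuffled, seed = 7)
  expect_equal(cal2$threshold, cal$threshold)
  expect_equal(cal2$calibration, cal$calibration)
  expect_false(identical(glance(cal2$validation), glance(cal$validation)))
})

test_that("external validation applies the frozen cut-point unchanged", {
  s <- tibble::tibble(
    subject_id = sprintf("C%02d", 1:40),
    scheme = "acsm_aha",
    mvpa_bout = c(rep(35, 15), rep(10, 25)),
    mvpa_nonbout = c(rep(95, 15), rep(12, 20), rep(90, 5))
  )
  d <- validate_cutpoint(s, threshold = 80)
  expect_equal(c(d$tp, d$fn, d$fp, d$tn), c(15, 0, 5, 20))
  expect_equal(d$lr_pos, 1 / (1 - 20 / 25))
  expect_error(validate_cutpoint(s, 80, scheme = "vo2r_50"), "no summaries")
})

test_that("regression equivalence matches closed-form least squares", {
  # normal equations by hand: slope 1.4, intercept 0.5
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(2, 3, 5, 6))
  r <- regression_equivalence(d, x, y, at = 10)
  expect_equal(r$slope, 1.4)
  expect_equal(r$intercept, 0.5)
  expect_equal(r$estimate, 0.5 + 1.4 * 10)
  expect_true(r$conf.low < r$estimate & r$estimate < r$conf.high)
  expect_true(r$pred.low <= r$conf.low & r$conf.high <= r$pred.high)

  # exact linear data: point prediction exact, intervals collapse
  e <- tibble::tibble(x = 1:6, y = 2 * (1:6))
  re <- regression_equivalence(e, x, y, at = 30)
  expect_equal(re$estimate, 60)
  expect_lt(re$conf.high - re$conf.low, 1e-8)

  # duplicating the data leaves the fit unchanged
  d2 <- dplyr::bind_rows(d, d)
  r2 <- regression_equivalence(d2, x, y, at = 10)
  expect_equal(r2$estimate, r$estimate)
  expect_equal(r2$slope, r$slope)

  expect_error(regression_equivalence(d[1:2, ], x, y, at = 1), "n >= 3")
  flat <- tibble::tibble(x = rep(2, 5), y = rnorm(5))
  expect_error(regression_equivalence(flat, x, y, at = 2), "zero variance")
})

test_that("roc and calibration objects print and plot", {
  r <- roc_curve(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_output(print(r), "AUC")
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  expect_identical(auc_grade(c(0.95, 0.85, 0.75, 0.5)),
                   c("excellent", "good", "fair", "poor"))
})
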