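#' Configure an end-to-end analysis run
#'
#' Collects every knob of the pipeline in one schema-validated list:
#' either a [cohort_spec()] to simulate, or paths to a subject table and a
#' directory of per-subject trace files; the cut-point schemes; the bout
#' definition; the wear-validity thresholds; the bout-MVPA reference
#' criterion and split-sample settings. The resolved configuration is
#' written next to the outputs of every run, so any report can be
#' regenerated from its directory alone. Configurations round-trip
#' through YAML.
#'
#' @param cohort A [cohort_spec()] (simulated input), or `NULL` when
#'   reading files.
#' @param subjects_file,trace_dir Input files (used when `cohort` is
#'   `NULL`): a subject table readable by [read_subjects()] and a
#'   directory containing `<subject_id>.csv` traces.
#' @param schemes Cut-point schemes to analyze.
#' @param bout A [bout_definition()].
#' @param min_wear_hours,min_valid_days,min_weekdays,weekend_days_required
#'   Wear-validity thresholds, see [is_valid_assessment()].
#' @param reference_minutes Bout-MVPA criterion for calibration (default
#'   30 min/day).
#' @param split_ratio,split_seed Split-sample settings.
#' @param calibration_group Group calibrated on (default `"healthy"`);
#'   every other group is externally validated at the frozen cut-point.
#' @param seed Seed for simulation.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            subjects_file = NULL, trace_dir = NULL,
                            schemes = met_schemes(),
                            bout = bout_definition(),
                            min_wear_hours = 12, min_valid_days = 5,
                            min_weekdays = 3, weekend_days_required = 2,
                            reference_minutes = 30,
                            split_ratio = 2, split_seed = 1L,
                            calibration_group = "healthy",
                            seed = NULL) {
  if (is.null(cohort) && (is.null(subjects_file) || is.null(trace_dir))) {
    abort("either a cohort spec or subjects_file + trace_dir is required")
  }
  schemes <- match.arg(schemes, met_schemes(), several.ok = TRUE)
  if (!is.null(seed) && !is.null(cohort)) cohort$seed <- seed
  structure(
    list(cohort = cohort, subjects_file = subjects_file,
         trace_dir = trace_dir, schemes = schemes, bout = bout,
         min_wear_hours = min_wear_hours, min_valid_days = min_valid_days,
         min_weekdays = min_weekdays,
         weekend_days_required = weekend_days_required,
         reference_minutes = reference_minutes,
         split_ratio = split_ratio, split_seed = split_seed,
         calibration_group = calibration_group, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) -> wear validity -> daily and per-subject MVPA under
#' every scheme -> energy expenditure and PAL -> active/inactive
#' classification -> split-sample calibration of the non-bout cut-point
#' with held-out and external validation. Writes five delimited-text
#' report files plus the resolved configuration to `output_dir`:
#'
#' * `cohort_characteristics.csv` - per-group demographics, PAL and wear
#'   time (median \[IQR\] / mean (SD)).
#' * `mvpa_summary.csv` - median \[IQR\] MVPA per group x scheme, bout and
#'   non-bout.
#' * `calibration.csv` - per-scheme cut-point, sensitivity, specificity
#'   and AUC with confidence intervals (calibration half).
#' * `validation.csv` - frozen-cut-point performance in the held-out half
#'   and in each non-calibration group.
#' * `exclusions.csv` - per-subject validity ledger with the reason for
#'   every exclusion.
#'
#' Runs are deterministic given the configuration and seeds. Any stage
#' failure aborts with a stage-named error.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for report files (created if needed).
#' @return Invisibly, a list with the in-memory results: `profiles`,
#'   `assessments`, `summaries`, `energy`, `targets`, `calibration`,
#'   `external`, `tables` (the report tibbles).
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
  }

  # --- input -------------------------------------------------------------
  input <- stage("input", {
    if (!is.null(config$cohort)) {
      generate_cohort(config$cohort)
    } else {
      profiles <- read_subjects(config$subjects_file)
      records <- purrr::map(profiles$subject_id, function(id) {
        read_trace(file.path(config$trace_dir, paste0(id, ".csv"))) |>
          mutate(subject_id = id, .before = 1)
      }) |> bind_rows()
      list(profiles = profiles, records = records)
    }
  })
  profiles <- input$profiles
  records <- input$records

  # --- wear validity -----------------------------------------------------
  days <- stage("wear_validity",
                summarize_days(records, config$min_wear_hours))
  assessments <- stage("wear_validity", {
    a <- is_valid_assessment(days, config$min_valid_days,
                             config$min_weekdays,
                             config$weekend_days_required)
    if (!any(a$valid)) abort("no valid assessments")
    a
  })
  exclusions <- assessments |>
    left_join(select(profiles, "subject_id", "group"), by = "subject_id")

  # --- MVPA --------------------------------------------------------------
  summaries <- stage("bout_analysis", {
    daily <- daily_mvpa(records, profiles, config$schemes, config$bout)
    summarize_mvpa(daily, days, assessments) |>
      left_join(select(profiles, "subject_id", "group"), by = "subject_id")
  })

  # --- energy / PAL ------------------------------------------------------
  energy <- stage("energy_pal",
                  summarize_energy(records, profiles, days, assessments) |>
                    left_join(select(profiles, "subject_id", "group"),
                              by = "subject_id"))

  # --- classification ----------------------------------------------------
  targets <- stage("activity_classification", {
    bout30 <- summaries |>
      filter(.data$scheme == "acsm_aha") |>
      mutate(active_bout = classify_active(
        dplyr::pick(dplyr::everything()), target_mvpa_bout(config$reference_minutes)))
    pal <- energy |>
      mutate(active_pal = classify_active(dplyr::pick(dplyr::everything()),
                                          target_pal()))
    bout30 |>
      select("subject_id", "group", "active_bout") |>
      left_join(select(pal, "subject_id", "active_pal"), by = "subject_id")
  })

  # --- calibration / validation ------------------------------------------
  cal_sum <- summaries |> filter(.data$group == config$calibration_group)
  calibration <- stage("cutpoint_calibration",
                       calibrate_and_validate(
                         cal_sum, config$reference_minutes,
                         config$split_ratio, config$split_seed,
                         config$schemes))
  other_groups <- setdiff(unique(profiles$group), config$calibration_group)
  external <- stage("cutpoint_calibration", {
    purrr::map(other_groups, function(g) {
      validate_cutpoint(summaries |> filter(.data$group == g),
                        calibration$threshold, config$reference_minutes,
                        calibration$best_scheme)
    }) |> setNames(other_groups)
  })

  # --- report tables -----------------------------------------------------
  tables <- stage("report", {
    characteristics <- profiles |>
      semi_join(filter(assessments, .data$valid), by = "subject_id") |>
      left_join(select(energy, "subject_id", "pal"), by = "subject_id") |>
      left_join(days |>
                  group_by(.data$subject_id) |>
                  summarise(wear_hours = mean(.data$wear_minutes) / 60,
                            .groups = "drop"),
                by = "subject_id") |>
      group_by(.data$group) |>
      summarise(
        n = dplyr::n(),
        age_mean = mean(.data$age), age_sd = sd(.data$age),
        pct_male = 100 * mean(.data$sex == "male"),
        mets_max_mean = mean(.data$mets_max),
        mets_max_sd = sd(.data$mets_max),
        pal = fmt_med_iqr(median(.data$pal, na.rm = TRUE),
                          quantile(.data$pal, 0.25, na.rm = TRUE, names = FALSE),
                          quantile(.data$pal, 0.75, na.rm = TRUE, names = FALSE),
                          digits = 2),
        wear_hours_mean = mean(.data$wear_hours),
        wear_hours_sd = sd(.data$wear_hours),
        .groups = "drop"
      )

    mvpa_table <- summaries |>
      tidyr::pivot_longer(c("mvpa_nonbout", "mvpa_bout"),
                          names_to = "analysis", values_to = "minutes") |>
      group_by(.data$group, .data$scheme, .data$analysis) |>
      summarise(med_iqr(.data$minutes), .groups = "drop") |>
      mutate(formatted = fmt_med_iqr(.data$median, .data$q1, .data$q3))

    calib_table <- tidy(calibration) |>
      mutate(across(c("optimal_sens", "optimal_spec"), ~ 100 * .x))

    val_rows <- c(
      list(held_out = calibration$validation),
      external
    )
    validation_table <- purrr::imap(val_rows, function(d, nm) {
      glance(d) |> mutate(sample = nm, .before = 1)
    }) |>
      bind_rows() |>
      mutate(threshold = calibration$threshold,
             scheme = calibration$best_scheme)

    list(characteristics = characteristics, mvpa = mvpa_table,
         calibration = calib_table, validation = validation_table,
         exclusions = exclusions)
  })

  stage("report", {
    readr::write_csv(tables$characteristics,
                     file.path(output_dir, "cohort_characteristics.csv"))
    readr::write_csv(tables$mvpa, file.path(output_dir, "mvpa_summary.csv"))
    readr::write_csv(tables$calibration,
                     file.path(output_dir, "calibration.csv"))
    readr::write_csv(tables$validation,
                     file.path(output_dir, "validation.csv"))
    readr::write_csv(tables$exclusions,
                     file.path(output_dir, "exclusions.csv"))
    yaml::write_yaml(config_to_list(config),
                     file.path(output_dir, "config_resolved.yml"))
  })

  invisible(list(profiles = profiles, assessments = assessments,
                 summaries = summaries, energy = energy, targets = targets,
                 calibration = calibration, external = external,
                 tables = tables))
}

# Serializable view of a pipeline_config (S3 lists flattened to plain
# key-value structures for YAML round-tripping).
config_to_list <- function(config) {
  x <- unclass(config)
  if (!is.null(x$cohort)) {
    ch <- unclass(x$cohort)
    ch$start_date <- as.character(ch$start_date)
    ch$healthy <- unclass(ch$healthy)
    ch$copd <- unclass(ch$copd)
    x$cohort <- ch
  }
  x$bout <- unclass(x$bout)
  x
}
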