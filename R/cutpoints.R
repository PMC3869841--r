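#' Guideline MET cut-point schemes
#'
#' The four schemes map a subject to the MET threshold that defines
#' moderate-to-vigorous physical activity (MVPA):
#'
#' * `acsm_aha` - 3.0 METs for all ages (ACSM/AHA 2007).
#' * `acsm_aha_older` - 3.0 METs up to age 65; above 65, the individual
#'   threshold at 50% of oxygen-uptake reserve (ACSM/AHA 2007, older adults).
#' * `vo2r_50` - individual threshold at 50% of oxygen-uptake reserve for
#'   every subject.
#' * `acsm_2011` - 4.0 METs up to age 65, 3.2 METs above 65 (ACSM Position
#'   Stand 2011).
#'
#' @return Character vector of scheme names.
#' @export
met_schemes <- function() {
  c("acsm_aha", "acsm_aha_older", "vo2r_50", "acsm_2011")
}

#' MET threshold for a cut-point scheme
#'
#' The 50% oxygen-uptake-reserve threshold expresses VO2 reserve
#' (peak VO2 minus resting VO2) in METs. With resting metabolism taken as
#' `resting_mets` (1 MET, i.e. 3.5 ml O2 kg^-1 min^-1, by the standard ACSM
#' convention), the threshold is
#' `resting_mets + 0.5 * (mets_max - resting_mets)`. A measured resting
#' value, when available, can be supplied to override the convention.
#' Age comparisons use completed years, with 65 itself on the younger side
#' ("<= 65"), and all threshold comparisons downstream are inclusive.
#'
#' @param profiles Profiles tibble with at least `age` and, for the
#'   reserve-based schemes, `mets_max`.
#' @param scheme One of [met_schemes()].
#' @param resting_mets Resting metabolic rate in METs used in the reserve
#'   calculation; scalar or one value per profile row.
#' @return Numeric vector of thresholds (METs), one per profile row.
#' @export
#' @examples
#' p <- tibble::tibble(age = c(62L, 70L), mets_max = c(8.3, 6.0))
#' met_threshold(p, "acsm_2011")   # 4.0, 3.2
#' met_threshold(p, "vo2r_50")     # 4.65, 3.5
met_threshold <- function(profiles, scheme, resting_mets = 1) {
  scheme <- match.arg(scheme, met_schemes())
  assert_columns(profiles, "age", "profiles")
  n <- nrow(profiles)
  resting <- rep_len(resting_mets, n)

  vo2r <- function() {
    if (!"mets_max" %in% names(profiles) || anyNA(profiles$mets_max)) {
      abort("scheme requires mets_max for every subject")
    }
    if (any(profiles$mets_max < 1)) abort("mets_max must be >= 1")
    resting + 0.5 * (profiles$mets_max - resting)
  }

  thr <- switch(scheme,
    acsm_aha = rep(3.0, n),
    acsm_2011 = if_else(profiles$age <= 65, 4.0, 3.2),
    vo2r_50 = vo2r(),
    acsm_aha_older = {
      older <- profiles$age > 65
      out <- rep(3.0, n)
      if (any(older)) out[older] <- vo2r()[older]
      out
    }
  )
  unname(thr)
}

#' Add per-subject thresholds for several schemes
#'
#' @param profiles Profiles tibble with `subject_id`, `age`, `mets_max`.
#' @param schemes Character vector of scheme names (default all four).
#' @inheritParams met_threshold
#' @return A long tibble `subject_id, scheme, threshold`.
#' @export
add_met_thresholds <- function(profiles, schemes = met_schemes(),
                               resting_mets = 1) {
  assert_columns(profiles, "subject_id", "profiles")
  purrr::map(schemes, function(s) {
    tibble(
      subject_id = profiles$subject_id,
      scheme = s,
      threshold = met_threshold(profiles, s, resting_mets)
    )
  }) |>
    bind_rows()
}

#' Classify a worn minute as MVPA
#'
#' A minute counts as MVPA when its MET value is at or above the threshold
#' (inclusive, matching the ">=" phrasing of the guidelines). Only worn
#' minutes may be classified: METs recorded while the monitor is off the
#' body are meaningless, so calling this on a non-wear minute is a contract
#' violation.
#'
#' @param mets Numeric vector of per-minute MET values.
#' @param threshold MET threshold (scalar or per-minute).
#' @param wear Logical wear flags (default all `TRUE`).
#' @return Logical vector: MVPA minute or not.
#' @export
classify_minute <- function(mets, threshold, wear = TRUE) {
  wear <- rep_len(wear, length(mets))
  if (any(!wear)) abort("classify_minute() called on a non-wear minute")
  mets >= threshold
}
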