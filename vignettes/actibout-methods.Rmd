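---
title: "Methods: bout and non-bout MVPA analysis with actibout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bout and non-bout MVPA analysis with actibout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actibout)
library(dplyr)
```

## The problem

Wearable activity monitors estimate energy expenditure minute by minute in
metabolic equivalents of task (METs; 1 MET is resting metabolism, about
3.5 ml O2 per kg per minute, conventionally 1 kcal per kg per hour). How
much moderate-to-vigorous physical activity (MVPA) a cohort appears to
perform depends heavily on two analysis choices that are often left
implicit:

1. **Which MET cut-point defines "moderate"** — guidelines variously use a
   fixed 3.0 METs, age-dependent cut-points (4.0 METs up to age 65, 3.2
   above), or an individual threshold at 50% of oxygen-uptake reserve.
2. **Whether MVPA must arrive in bouts** — most guidelines require
   episodes of at least 10 consecutive minutes, yet accelerometry is
   frequently summarized by simply counting all qualifying minutes.

Bout-based totals are severalfold lower than non-bout totals — roughly
2–4x in healthy older adults and up to 3–12x in chronic disease
populations such as COPD, where activity is fragmented. This package
implements the complete analysis chain needed to study these effects and,
centrally, to **calibrate a non-bout cut-point equivalent to the standard
"30 min/day in bouts" criterion** via split-sample ROC analysis, so that
bout-free accelerometry summaries can be interpreted against bout-based
guidelines.

## Cut-point schemes

`met_threshold()` resolves a subject to a MET threshold under four
schemes: `acsm_aha` (3.0 METs for all ages), `acsm_2011` (4.0 METs at age
<= 65, 3.2 above), `vo2r_50` (individual 50% of VO2 reserve), and
`acsm_aha_older` (3.0 METs up to 65, the reserve threshold above). All
threshold comparisons are inclusive (`>=`), matching the ">= 3.0 METs"
phrasing of the guidelines, and age 65 itself falls on the younger side.

Expressing 50% of VO2 reserve in METs requires a resting value. We use
the standard convention resting = 1 MET, giving

\[ \text{threshold} = 1 + 0.5\,(\text{METs}_{max} - 1), \]

so a healthy subject with a peak capacity of 8.3 METs gets 4.65 METs and
a COPD-typical subject with 6.01 METs gets 3.505 METs — between the two
absolute cut-points. A measured resting VO2, when available, can be
passed via `resting_mets` and overrides the convention; which of the two
a given study used is rarely reported, so both are supported and the
default is documented here.

## Bouts

A strict bout is a maximal run of at least `min_duration` (default 10)
consecutive minutes at or above the threshold. Non-wear and missing
minutes are below threshold by definition and terminate runs; bouts do
not cross midnight, because accumulation is per calendar day (a run
spanning midnight is split — a documented limitation shared with daily
accounting generally).

The interruption-tolerant variant (`bout_definition(10, t, "tolerant")`)
follows analyses that accept 1–2 below-threshold minutes inside a bout.
We define it by *coverage*: a qualifying window is any stretch of >=
`min_duration` minutes that starts and ends above threshold and contains
at most `t` interruption minutes; a minute counts as bout time when some
qualifying window covers it, and reported bouts are the connected unions
of such windows. This definition was chosen over greedy left-to-right
window selection because greedy selection is not monotone in the
tolerance (an early marginal window can exhaust the interruption budget
and block a longer bout downstream), whereas coverage provably satisfies

* bout minutes are monotone non-decreasing in `t`,
* tolerance 0 reduces exactly to strict runs,
* bouts are disjoint, ordered, and never start or end on an interruption.

One consequence to be aware of: a long bout assembled from overlapping
windows can contain more than `t` interruption minutes in total, although
every sub-stretch of it is witnessed by a window with at most `t`. All
minutes of a bout, including tolerated interruptions, count toward bout
MVPA. The detector is verified, strict and tolerant, against an
exhaustive all-windows oracle on randomized traces in the test suite.
The median-intensity bout definition used by some studies (a window
qualifying by its median METs) is out of scope.

## Wear time and valid assessments

The monitor's wear flag is taken as given (multisensor armbands detect
skin contact); missing epochs count as non-wear. A day is valid with at
least 12 h of wear (`min_wear_hours`, inclusive: 720 minutes pass). An
assessment is valid when the subject's valid days include the weekend,
at least 3 weekdays, and at least 5 days in total.

The phrase "weekend days" in such validity rules is ambiguous between
*both* weekend days and *at least one*; we default to requiring both a
valid Saturday and a valid Sunday (`weekend_days_required = 2`) and
expose the laxer reading as configuration. All downstream daily
averages — MVPA and PAL alike — are means over valid days only, and
subjects without a valid assessment are excluded from cohort statistics
with a named reason (`weekend_days`, `weekdays`, `valid_days`), checked
in that order so every exclusion is accounted for.

## Energy expenditure and PAL

METs convert to kilocalories at 1 kcal per kg per hour per MET (the
compendium convention; the coefficient is configurable). Daily total
energy expenditure is measured expenditure over worn minutes plus
imputed expenditure for non-wear time at the resting rate:

\[ \text{TEE} = \sum_{\text{worn min}} \text{METs} \cdot w/60
   \;+\; \text{non-wear min} \cdot \text{REE}/1440 . \]

The resting energy expenditure follows the wear protocol. Around-the-
clock wearers use measured whole-night sleeping energy expenditure: the
mean per-minute expenditure over sleep-flagged minutes, scaled to 24 h.
"Whole night" is operationalized as the longest sleep-flagged block per
day between 20:00 and 10:00, pooled across days, requiring at least 120
pooled minutes; otherwise the sex-specific Harris–Benedict prediction is
used with a warning. Waking-hours wearers always use Harris–Benedict.
The original 1919 coefficients are the default (men:
\(66.473 + 13.7516\,w + 5.0033\,h - 6.755\,a\); women:
\(655.0955 + 9.5634\,w + 1.8496\,h - 4.6756\,a\)), with the revised
Roza–Shizgal coefficients behind `variant = "revised"`.

PAL is TEE/REE, averaged over valid days. A week worn around the clock
at exactly 1 MET with sleep measured at 1 MET yields PAL = 1 exactly (a
test pins this). PAL below 1 is physiologically suspect (measured
expenditure below rest) and raises a data-quality warning. The activity
target is PAL >= 1.7, inclusive.

## Classification and diagnostic accuracy

Subjects are classified active/inactive against inclusive thresholds on
per-subject summaries: >= 30 min/day of bout MVPA, >= 1.7 PAL, or a
non-bout cut-point. The primary classification uses the mean over valid
days (as the ROC calibration does); a days-per-week reading (active on
>= 5 of 7 days) is available via `classify_weekly()`.

`diagnostic_accuracy()` cross-tabulates one target against another and
reports sensitivity, specificity, the false-positive rate, and the
positive likelihood ratio LR+ = sensitivity / (1 − specificity) — how
many times more likely a subject meeting the reference criterion is to
be labelled active by the index target. Confidence intervals use the
Wilson score method for proportions and the Simel log method for LR+;
neither choice is universal in the applied literature, and both were
selected for small-sample behaviour (Wald intervals misbehave at the
observed 86–98% sensitivities with n < 40) and are isolated behind the
object so they can be swapped. Zero false positives make LR+ infinite;
it is then reported with a one-sided interval whose lower bound uses
0.5-per-cell continuity correction, plus a warning.

## Split-sample calibration

`calibrate_and_validate()` partitions subjects 2:1 (the calibration size
is the nearest integer to \(2n/3\), ties toward calibration, so 110
subjects split 73/37), fits a ROC per scheme on the calibration half —
index: non-bout MVPA; reference: >= 30 min/day bout MVPA *under the same
scheme* — selects the scheme with the highest AUC, freezes its optimal
cut-point, and only then evaluates the held-out half at the frozen
cut-point. A permutation test in the suite verifies the holdout can
never influence the cut-point.

ROC construction uses all distinct observed values plus an upper
sentinel; the AUC is trapezoidal, which on every instance equals the
Mann–Whitney pair-counting estimator with ties counted one half (an
identity the suite asserts to 1e-12), with a DeLong-type placement
variance for its interval (cross-checked against an independent
implementation). "Sensitivity and specificity both maximized" is read as
Youden's J = sens + spec − 1, the standard interpretation when no index
is named; ties break toward the larger (more specific) cut-point, and
cut-points are reported in whole minutes, with the operating point
recomputed at the rounded value. AUCs are graded excellent (>= 0.90),
good (0.80–0.89), fair (0.70–0.79), poor (< 0.70).

`regression_equivalence()` complements the ROC route: an OLS fit of one
metric on another reports the predicted response at a target value with
both a confidence interval (mean response) and a prediction interval
(new subject); published equivalences of this kind do not always state
which interval they print, so both are emitted.

## The synthetic cohort

No minute-level dataset accompanies the analyses this package
implements, so `generate_cohort()` produces one with the statistical
structure the method assumes, and the whole pipeline is tested against
it. Each subject-day is built compositionally:

1. a sleep block (~480 min at ~0.95 METs, flagged sleep under the
   full-day protocol, absent as non-wear under waking hours),
2. long MVPA runs (>= 10 min) and short runs (< 10 min) placed at
   uniformly random, non-overlapping, non-adjacent positions in waking
   wear time (adjacency is forbidden so short runs cannot coalesce into
   spurious bouts — run structure is exactly controlled),
3. background intensity filling the remaining wear minutes below 3 METs,
4. non-wear minutes left absent (gaps).

MVPA-minute intensities are drawn at or above 3.2 METs — a margin above
the 3 MET line — so generator-side run structure translates exactly into
classification-side MVPA and the targets below are analytically
checkable. Daily run counts are Poisson around subject rates; a shared
lognormal subject scale (median 1) multiplies both rates, producing the
right-skewed cohort distributions seen in real data.

Group defaults were derived in closed form, once, from the target
medians for the 3 MET cut-point — healthy: 106 non-bout / 39 bout
min/day and PAL 1.64; COPD: 49 / 13 and PAL 1.50:

* healthy long bouts: rate 2.8/day x mean duration 14 min (10 +
  geometric, p = 0.2) = 39.2 bout min; short runs: rate 18.3/day x mean
  11/3 min (triangular weights on 1–9) = 67.1; total 106.3;
* COPD: 1.05/day x 12.5 min = 13.1 and 9.8/day x 11/3 = 35.9, total
  49.0;
* background intensity means (1.64 METs healthy, 1.33 COPD) solve the
  PAL identities at the group wear times (23.08 h full-day with
  sleep-measured REE — in which body weight cancels — and 16.87 h waking
  hours with Harris–Benedict REE for a typical male subject);
* subject-scale SDs (log scale 0.55 healthy, 1.0 COPD) reproduce the
  interquartile spans (e.g. 70–151 around 106, and 2–35 around 13 —
  COPD bout MVPA is far more dispersed).

Since 7-day means are unbiased for subject-level expectations and the
subject scale has median 1, cohort medians of weekly means land on the
configured targets; a 200-per-group cohort recovers all six within
+-15% in the acceptance suite, and calibration against the 30-minute
bout criterion recovers a non-bout cut-point near the configured
separability (30 x 106.3/39.2 ~ 81 min/day).

**What the generator does not emulate.** Day-to-day within-subject
variance is essentially unreported in published cohort summaries; the
Poisson-count choice is a documented free parameter. There is no
circadian structure beyond the sleep block, no sensor noise around the
3 MET line (by design, via the 3.2 margin), and bout and short-run
propensity share a single subject scale. That last choice makes non-bout
MVPA more predictive of bout status than in real cohorts — synthetic
calibration AUCs run ~0.97 against ~0.89 reported for real data — so
passing recovery tests demonstrates correctness of the pipeline, not
real-data discrimination. We kept the shared scale after checking that
decorrelating the two propensities moves the recovered cut-point away
from, not toward, the real-data value, while adding a parameter nothing
in the target structure constrains.

## Numerical conventions and degenerate inputs

* Median [IQR] report tables use linear-interpolation quantiles (R type
  7); the convention matters for small groups and is fixed here.
* Cut-points print as whole minutes; ROC ties break toward specificity.
* Epochs are left-labelled, half-open ([10:00, 10:01) is the minute
  stamped 10:00); days are local calendar days; weekend = Saturday and
  Sunday.
* Duplicate minutes, negative METs and malformed timestamps are hard
  errors naming the line — the reader never silently drops rows.
* Single-class references are errors everywhere (ROC, diagnostics,
  calibration halves), with a message advising a re-seed or larger
  cohort where a random split caused it.
* Problem sizes in the test suite — 200-per-group recovery cohorts,
  10^4 randomized traces against the bout oracle, 10^3 AUC identity
  instances — were chosen to exercise the estimators well past the
  study-sized n while keeping the default `devtools::test()` run in the
  low minutes.

## Worked example

```{r example, eval = FALSE}
coh <- generate_cohort(cohort_spec(n_healthy = 110, n_copd = 113,
                                   seed = 1))
days <- summarize_days(coh$records)
ok <- is_valid_assessment(days)
summaries <- summarize_mvpa(daily_mvpa(coh$records, coh$profiles,
                                       "acsm_aha"),
                            days, ok) |>
  dplyr::left_join(dplyr::select(coh$profiles, subject_id, group),
                   by = "subject_id")

cal <- calibrate_and_validate(dplyr::filter(summaries, group == "healthy"),
                              seed = 2, schemes = "acsm_aha")
cal$threshold          # derived non-bout cut-point (min/day)
glance(cal)            # AUC and held-out operating point
validate_cutpoint(dplyr::filter(summaries, group == "copd"),
                  cal$threshold)
```

## Limitations

Beyond the generator caveats above: the pipeline ingests the
manufacturer's MET estimates as given (no raw-sensor modelling); bout
splitting at midnight slightly undercounts overnight activity; and the
interruption-tolerant accounting (interruptions count toward bout
minutes) is one of several conventions in use — strict bouts, the
default everywhere, are unaffected.
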