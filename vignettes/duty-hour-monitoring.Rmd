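---
title: "Measuring duty-hour violations from EHR access logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring duty-hour violations from EHR access logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dutyhours)
```

## The problem

Accredited training programs must monitor resident duty hours, but the
dominant instrument is self-report, which is onerous and vulnerable to
recall bias and to deliberate under-reporting. EHR audit logs offer an
objective alternative: every chart open, order, and note edit leaves a
timestamp, and a trainee's stream of in-hospital timestamps traces out
their working day. `dutyhours` implements the full chain from raw audit
rows to a block-level comparison of EHR-defined violations (EDV) against
self-reported violations (SRV), plus a generative simulator so every stage
can be validated against known ground truth.

## Shift inference by gap-threshold sessionization

For one trainee, events are sorted and consecutive gaps computed
(`compute_intervals()`). A shift candidate is a maximal run of events whose
internal gaps are all strictly below `long_gap_threshold`
(`segment_shifts()`); refinement (`refine_shifts()`) then merges candidates
separated by less than `merge_gap` and discards candidates shorter than
`min_shift_duration`, in that order, so two close fragments can survive as
one merged shift.

The three parameters (minutes) are exposed in `segmentation_params()`, never
hard-coded:

* `long_gap_threshold = 300`. Five hours exceeds any plausible on-shift idle
  stretch (even a quiet overnight call produces intermittent chart checks)
  but is well below the shortest legal rest period (8 h), so true shift
  boundaries always present a longer gap than true idle time.
* `merge_gap = 60`, `min_shift_duration = 60`. A shift interrupted by under
  an hour of EHR silence is one shift; an isolated sub-hour fragment is more
  likely a stray login than a shift.
* `start_pad` / `end_pad` (default 0) extend endpoints outward for work done
  before the first and after the last EHR event. With the default of zero
  the method can under-estimate but never over-estimate time on duty.

Ties are declared, not incidental: a gap *exactly equal* to the threshold
starts a new shift. The test suite checks the implementation against a
brute-force boundary-marking oracle on a thousand random minute-resolution
streams, and checks that raising the threshold can only reduce the shift
count.

## The duty-hour rule engine

`duty_hour_rules()` encodes the era's limits: a 16 h (960 min) continuous
cap for junior front-line clinicians (interns), 28 h (24+4 h) for senior
front-line and supervisory trainees, 8 h required rest after shifts of at
most 16 h and 14 h after longer shifts. Boundary conventions are explicit
and tested one minute to each side of every threshold:

* a shift of exactly the cap is legal (`DURATION` requires strict excess);
* the short-rest class is inclusive (a 960-min shift needs 480 min rest);
* rest exactly equal to the requirement is adequate (`INTERVAL` requires a
  strict shortfall).

The 24+4 allowance is implemented as a single 28 h cap — no separate
transition-window bookkeeping — and weekly-hour or day-off rules are out of
scope. Interval checks examine adjacent shift pairs only, cross block
boundaries, and attribute the violation to the later shift's block. The
engine is source-agnostic: run on EHR-defined shifts it produces EDV, on
self-reports SRV, with identical conventions.

## Blocks, tallies, and the paired comparison

The academic year is divided into thirteen contiguous blocks (28 days,
with 29 on the first and last). A shift belongs to the block containing its
*start* on the local calendar date in the configured reference timezone
(default `America/New_York`), so a 28 h call launched on a block's last day
counts in that block. All instants are stored in UTC; wall-clock is used
only for this block-date lookup, which keeps duration arithmetic immune to
daylight-saving transitions.

`tally_blocks()` produces one row per resident-block (trainee x block x
rotation) with shift and violation counts by source and type; blocks with
no shifts of a source carry explicit zeros. Blocks with *no* self-reported
shifts are excluded from all paired analyses (`exclude_unlogged_blocks()`),
with block- and trainee-level exclusion percentages reported to one
decimal. `paired_difference()` classifies each eligible block by the sign
of SRV − EDV; UNDER blocks (fewer self-reported than EHR-defined
violations) are the under-reporting signature.

Role contrasts use one-way ANOVA with Tukey HSD post-hoc adjustment
(`role_summary()`; SEM uses the n−1 sample standard deviation). The
source effect is estimated by ordinary least squares on the long form
(one row per block x source): `total ~ source_SRV + role_SR_FLC +
role_SR_SUPRV`. Linear rather than count regression mirrors the reporting
of a mean per-block difference with a symmetric standard error; a
negative-binomial variant would be a reasonable extension but is not the
default, and no trainee-level random effect is included. Rank deficiency
(e.g., a single-role cohort) raises an explicit error naming the collinear
column rather than silently dropping it. Both the ANOVA/Tukey path and the
OLS path are verified against independent closed-form implementations
(direct sums of squares, the studentized-range distribution, and the
normal equations) to 1e-8.

## What the simulator emulates

`simulate_study()` generates the five ingest tables plus ground truth:

* **Cohort.** Role mix defaults to 44/40/16% junior front-line / senior
  front-line / senior supervisory at block level; juniors are PGY-1,
  seniors PGY 2–4. Each trainee works all thirteen blocks, drawing a
  rotation per block with role-specific odds of a q4-call service.
* **Schedules.** Two deterministic templates: every-fourth-night call
  (17 slots per 28-day block) and day–night 12 h shifts (23 slots), the
  documented range for inpatient services of this kind. Call slots are
  role-sized: a senior call is scheduled 60 min short of the 28 h cap, a
  junior "call" is a 16 h long-day. Templates leave the block's final day
  clear so consecutive blocks can never overlap.
* **Seeded violations.** Duration violations arise only on call slots: with
  role-specific probability the shift overruns the cap by a lognormal
  excess (median ≈ 36 min, quartiles ≈ 16 and 70 min, clamped at 4 h) —
  the magnitude distribution reported for real over-cap shifts. Interval
  violations arise from early call-ins that realize only 65–92% of the
  required rest. Because overage is confined to slots followed by at least
  two clear days, a seeded duration excess can never mechanically force a
  rest violation or an overlap, and every inter-shift gap stays above the
  312-min floor — hence above the 300-min segmentation threshold, the
  separation condition for exact shift recovery. The per-role probabilities
  are calibration inputs chosen to give per-block violation means near
  0.6 / 2.3 / 1.4 for the three roles; they are inputs, not findings.
* **Event process.** Within a shift, events follow a homogeneous Poisson
  process (mean gap 30 min) with gaps clamped at 240 min; the first and
  last events fall within configurable lag/lead of the true boundaries
  (default 0). Real EHR usage is burstier, but sessionization depends only
  on the gap cap, so the simple process is sufficient for what the
  recovery tests claim. Off-site noise events can be added at a per-day
  rate on off-site workstations.
* **Reporting behavior.** Mechanistic and independently switchable: 17% of
  trainees log nothing all year; a reporter's block goes unlogged with
  probability 0.06 (marginal unlogged-block rate ≈ 22%); individual shifts
  are omitted at 3%; an over-cap shift is reported as ending exactly at the
  cap with probability 0.7 (erasing the violation from the self-report);
  Gaussian endpoint jitter (sd 10 min) and optional rounding are applied
  last. `zero_reporting_behavior()` makes self-reports verbatim truth.

## What passing tests do and do not show

Exact end-to-end recovery (seeds 1–50, 20 trainees x 13 blocks) holds
*under the separation condition with zero lag/lead*; it demonstrates the
pipeline's internal correctness, not the field accuracy of the 300-min
heuristic on real audit logs, which depends on usage patterns the
homogeneous event process does not model. With positive lag/lead the
pipeline provably never over-counts violations relative to truth — the
conservative direction — and the under-reporting analysis (100 seeds,
75 trainees, ≥ 600 eligible blocks per seed) recovers a negative source
coefficient with p < 0.05 in ≥ 90% of seeds. One asymmetry is expected:
with zero lag/lead no mechanism inflates self-reports above truth, so
simulated over-reporting sits near 0% while real cohorts show an
appreciable OVER fraction, attributed to work beyond the bounds of EHR
use; positive lag/lead reproduces that direction qualitatively. The
simulator also ignores outpatient-clinic afternoons, circadian structure,
and any correlation between workload and reporting diligence.

## Numerical conventions and degenerate inputs

Timestamps are parsed as ISO 8601, normalized to UTC, and generated at
whole-second resolution so CSV round-trips are exact. Exact duplicate
audit rows are collapsed; same-second rows with different event codes are
retained (the algorithm consumes only timestamps). Unknown workstations
are treated as on-site with a warning tally — exclusion is evidence-based.
Empty event sets yield empty shift lists; a single event yields a
zero-duration candidate that refinement discards; quantiles of excess
duration use type-7 linear interpolation; an empty violation set yields
`n = 0` with `NA` quantiles rather than an error. Inference with fewer
than two roles of two or more blocks degrades to descriptives with a
warning.

## Reference problem sizes

The validation suite uses 1,000 random streams of up to 200 events for the
segmentation oracle, 50 simulated years of 20 trainees for exact recovery,
10 for the lag/lead under-count bound, and 100 simulated years of 75
trainees for the under-reporting recovery; the analysis scripts under
`analysis/` use one 60-trainee year. These sizes give stable Monte-Carlo
behavior (the eligible-block count stays above 600 in every seed) while a
full run of scripts and tests completes in minutes on a laptop.
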