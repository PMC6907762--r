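#!/usr/bin/env Rscript
# Stage 1 — simulate one academic year of a pediatric residency program:
# roster (junior/senior front-line and supervisory roles over 13 four-week
# blocks), ground-truth shifts on q4-call and day-night templates, the EHR
# access-log event stream those shifts generate, and biased self-reports.
# Raw inputs land in scratch/sim/ (they are large); a compact summary goes
# to results/.

suppressMessages({
  library(dutyhours)
  library(dplyr)
})

seed <- 1L
sim <- simulate_study(
  n_trainees = 60L, seed = seed,
  event_params = event_process_params(offsite_rate_per_day = 0.3)
)
paths <- write_simulated_inputs(sim, "scratch/sim")

summary <- tibble::tibble(
  seed = seed,
  n_trainees = dplyr::n_distinct(sim$roster$trainee_id),
  n_resident_blocks = nrow(sim$roster),
  n_true_shifts = nrow(sim$true_shifts),
  n_events = nrow(sim$events),
  n_self_reported_shifts = nrow(sim$self_reports),
  n_true_violations = nrow(sim$true_violations)
)
dir.create("results", showWarnings = FALSE)
readr::write_csv(summary, "results/simulation_summary.csv")

cat(sprintf(
  "Simulated %d trainees over %d resident-blocks (seed %d):\n  %d true shifts -> %d access-log events; %d self-reported shifts\n  %d ground-truth duty-hour violations\nInputs written to %s\n",
  summary$n_trainees, summary$n_resident_blocks, seed, summary$n_true_shifts,
  summary$n_events, summary$n_self_reported_shifts, summary$n_true_violations,
  dirname(paths[[1]])
))
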