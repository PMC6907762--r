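#!/usr/bin/env Rscript
# Stage 4 — the cohort comparison: resident-block tallies of EHR-defined
# (EDV) and self-reported (SRV) violations, exclusion of blocks with no
# self-reported shifts, role summaries with ANOVA/Tukey, the paired
# SRV - EDV distribution, and the multivariable model of total violations
# on source and role. A negative source coefficient quantifies systematic
# under-reporting.

suppressMessages({
  library(dutyhours)
  library(dplyr)
})

# readr parses the ISO 8601 "Z" timestamps straight to POSIXct in UTC
read_shift_csv <- function(path, source) {
  readr::read_csv(path, show_col_types = FALSE) |>
    transmute(trainee_id, start, end, source = source,
              duration_minutes = as.numeric(difftime(end, start, units = "mins")))
}

eds <- read_shift_csv("scratch/sim/eds.csv", "EHR_DEFINED")
srs <- read_self_reports("scratch/sim/self_reports.csv")
roster <- read_roster("scratch/sim/roster.csv")
calendar <- read_block_calendar("scratch/sim/blocks.csv")

res <- compare_cohort(eds, srs, roster, calendar)

readr::write_csv(res$tallies, "results/tallies.csv")
readr::write_csv(res$exclusion, "results/exclusion_report.csv")
readr::write_csv(res$paired$summary, "results/paired_summary.csv")
readr::write_csv(res$paired$histogram, "results/paired_histogram.csv")
readr::write_csv(res$role_edv$summary, "results/role_summary_edv.csv")
readr::write_csv(res$role_srv$summary, "results/role_summary_srv.csv")
readr::write_csv(res$role_edv$tukey, "results/tukey_edv.csv")
readr::write_csv(res$model$coefficients, "results/model_coefficients.csv")
jsonlite::write_json(
  list(coefficients = res$model$coefficients,
       anova_edv = res$role_edv$anova,
       paired = res$paired$summary),
  "results/model_fit.json", auto_unbox = TRUE, digits = NA, dataframe = "rows"
)

rs <- res$role_edv$summary
src <- res$model$coefficients |> filter(term == "source_SRV")
cat(sprintf(
  paste0(
    "Mean EDV per resident-block by role: Jr FLC %.2f±%.2f, Sr FLC %.2f±%.2f, Sr Suprv %.2f±%.2f (ANOVA p = %.2g).\n",
    "%d of %d blocks (%.1f%%) had zero self-reported shifts and were excluded from paired analysis.\n",
    "Of the eligible blocks, %.1f%% under-reported (SRV < EDV) and %.1f%% over-reported.\n",
    "Adjusted for role, SRV were %.2f±%.2f violations per block relative to EDV (p = %.2g).\n"
  ),
  rs$mean[1], rs$sem[1], rs$mean[2], rs$sem[2], rs$mean[3], rs$sem[3],
  res$role_edv$anova$p,
  res$exclusion$n_blocks_excluded, res$exclusion$n_blocks_total,
  res$exclusion$pct_blocks_excluded,
  res$paired$summary$pct_under, res$paired$summary$pct_over,
  src$estimate, src$std_error, src$p_value
))
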