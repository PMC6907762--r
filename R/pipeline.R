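#' Load pipeline configuration from YAML
#'
#' Recognized blocks: `paths:` (the five input CSVs), `segmentation:`
#' (arguments of [segmentation_params()]), `rules:` (arguments of
#' [duty_hour_rules()]), `reference_tz:`, `output_dir:`, `seed:`. Omitted
#' blocks fall back to package defaults; unknown keys inside a block raise
#' an error rather than being silently ignored.
#'
#' @param path YAML file path.
#' @return A list with `paths`, `segmentation`, `rules`, `reference_tz`,
#'   `output_dir`, `seed`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  call_with <- function(fn, args, block) {
    args <- args %||% list()
    unknown <- setdiff(names(args), names(formals(fn)))
    if (length(unknown) > 0L) {
      stop(sprintf("config block `%s`: unknown key(s): %s", block,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    do.call(fn, args)
  }
  list(
    paths = cfg$paths %||% list(),
    segmentation = call_with(segmentation_params, cfg$segmentation, "segmentation"),
    rules = call_with(duty_hour_rules, cfg$rules, "rules"),
    reference_tz = cfg$reference_tz %||% "America/New_York",
    output_dir = cfg$output_dir %||% "results",
    seed = cfg$seed %||% 1L
  )
}

#' Compare EHR-defined and self-reported violations across a cohort
#'
#' The full downstream analysis over two shift tables: block assignment,
#' duty-hour violation detection for both sources, resident-block tallies,
#' exclusion of blocks with no self-reported shifts, the paired SRV - EDV
#' distribution, role summaries with ANOVA/Tukey (EDV over all blocks; SRV
#' over the SRS-eligible blocks), the excess-duration quantiles over
#' EHR-defined duration violations, and the multivariable OLS model of
#' total violations on source and role.
#'
#' @param eds EHR-defined shift tibble (e.g. from [infer_all_shifts()]).
#' @param srs Self-reported shift tibble.
#' @param roster Roster tibble.
#' @param calendar Block calendar.
#' @param rules A [duty_hour_rules()] object.
#' @param tz Reference timezone for block assignment.
#' @return A list: `tallies`, `violations`, `exclusion` (report tibble),
#'   `paired` (list from [paired_difference()]), `role_edv`, `role_srv`,
#'   `excess` (one-row tibble), `model` (list from [fit_violation_model()]).
#' @export
compare_cohort <- function(eds, srs, roster, calendar,
                           rules = duty_hour_rules(), tz = "America/New_York") {
  keep <- c("trainee_id", "start", "end", "source", "duration_minutes")
  shifts <- dplyr::bind_rows(eds[intersect(keep, names(eds))],
                             srs[intersect(keep, names(srs))])
  assigned <- assign_blocks(shifts, calendar, roster, tz = tz)
  violations <- detect_violations(assigned, rules)
  tallies <- tally_blocks(assigned, violations, roster)
  excl <- exclude_unlogged_blocks(tallies)
  paired <- paired_difference(excl$eligible)
  role_edv <- role_summary(tallies, "EHR_DEFINED")
  role_srv <- role_summary(excl$eligible, "SELF_REPORTED")
  excess <- excess_duration_stats(
    dplyr::filter(violations, .data$source == "EHR_DEFINED")
  )
  model <- fit_violation_model(excl$eligible)
  list(tallies = tallies, violations = violations, exclusion = excl$report,
       eligible = excl$eligible, paired = paired,
       role_edv = role_edv, role_srv = role_srv, excess = excess, model = model)
}
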