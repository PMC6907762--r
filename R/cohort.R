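#' Assign shifts to scheduling blocks and roster roles
#'
#' Each shift is assigned to the block containing its *start* instant
#' (half-open block intervals `[start_date, next_start)`), evaluated on the
#' local calendar date in the reference timezone. A 28-hour call beginning
#' on a block's last day therefore counts in that block. Role and rotation
#' are joined from the roster.
#'
#' @param shifts Shift tibble (any mix of sources).
#' @param calendar Block calendar from [read_block_calendar()] /
#'   [make_academic_calendar()].
#' @param roster Roster tibble from [read_roster()] / [generate_cohort()].
#' @param tz Reference timezone for wall-clock block dates.
#' @return The shifts annotated with `block_id`, `role`, `rotation`.
#'   Trainee-blocks with shifts but no roster assignment are dropped with a
#'   warning; the dropped rows are attached as attribute `excluded_shifts`.
#' @export
assign_blocks <- function(shifts, calendar, roster, tz = "America/New_York") {
  local_date <- as.Date(format(shifts$start, "%Y-%m-%d", tz = tz))
  idx <- findInterval(as.numeric(local_date), as.numeric(calendar$start_date))
  n_blocks <- nrow(calendar)
  out_of_range <- idx == 0L | local_date >= calendar$end_date[n_blocks]
  if (any(out_of_range)) {
    off <- shifts[out_of_range, , drop = FALSE]
    stop(sprintf("shift start outside block calendar for: %s",
                 paste(utils::head(sprintf("%s@%s", off$trainee_id, fmt_utc(off$start)), 5L),
                       collapse = "; ")), call. = FALSE)
  }
  out <- shifts
  out$block_id <- calendar$block_id[idx]
  out <- dplyr::left_join(out, roster[c("trainee_id", "block_id", "role", "rotation")],
                          by = c("trainee_id", "block_id"))
  unassigned <- is.na(out$role)
  excluded <- out[unassigned, , drop = FALSE]
  if (nrow(excluded) > 0L) {
    warning(sprintf("%d shift(s) in %d trainee-block(s) without roster assignment excluded",
                    nrow(excluded),
                    nrow(unique(excluded[c("trainee_id", "block_id")]))), call. = FALSE)
    out <- out[!unassigned, , drop = FALSE]
  }
  attr(out, "excluded_shifts") <- excluded
  out
}

#' Tally shifts and violations per resident-block
#'
#' A resident-block is one trainee on one rotation during one scheduling
#' block. Every roster assignment yields one tally row; blocks with no
#' shifts of a source carry zero counts for that source. EDV/SRV columns
#' count violations over EHR-defined / self-reported shifts respectively.
#'
#' @param shifts Block-assigned shifts from [assign_blocks()].
#' @param violations Violations from [detect_violations()] over those
#'   shifts (they must reference shifts present in `shifts`).
#' @param roster Roster tibble defining the resident-blocks.
#' @return A tibble with one row per resident-block: `trainee_id, block_id,
#'   role, rotation, n_eds, n_srs, edv_duration, edv_interval, edv_total,
#'   srv_duration, srv_interval, srv_total`.
#' @export
tally_blocks <- function(shifts, violations, roster) {
  if (nrow(violations) > 0L) {
    known <- paste(shifts$trainee_id, shifts$source, fmt_utc(shifts$start))
    ref <- paste(violations$trainee_id, violations$source, fmt_utc(violations$shift_start))
    if (!all(ref %in% known)) {
      stop("violation references a shift not present in `shifts`", call. = FALSE)
    }
  }
  base <- roster[c("trainee_id", "block_id", "role", "rotation")]
  shift_counts <- shifts |>
    dplyr::count(.data$trainee_id, .data$block_id, .data$source) |>
    tidyr::pivot_wider(names_from = "source", values_from = "n", values_fill = 0L)
  for (col in c("EHR_DEFINED", "SELF_REPORTED")) {
    if (!col %in% names(shift_counts)) shift_counts[[col]] <- 0L
  }
  viol_counts <- violations |>
    dplyr::count(.data$trainee_id, .data$block_id, .data$source, .data$type) |>
    dplyr::mutate(col = paste0(ifelse(.data$source == "EHR_DEFINED", "edv_", "srv_"),
                               tolower(.data$type))) |>
    dplyr::select("trainee_id", "block_id", "col", "n") |>
    tidyr::pivot_wider(names_from = "col", values_from = "n", values_fill = 0L)
  out <- base |>
    dplyr::left_join(dplyr::rename(shift_counts, n_eds = "EHR_DEFINED",
                                   n_srs = "SELF_REPORTED"),
                     by = c("trainee_id", "block_id")) |>
    dplyr::left_join(viol_counts, by = c("trainee_id", "block_id"))
  for (col in c("n_eds", "n_srs", "edv_duration", "edv_interval",
                "srv_duration", "srv_interval")) {
    if (!col %in% names(out)) out[[col]] <- 0L
    out[[col]] <- dplyr::coalesce(out[[col]], 0L)
  }
  out |>
    dplyr::mutate(edv_total = .data$edv_duration + .data$edv_interval,
                  srv_total = .data$srv_duration + .data$srv_interval) |>
    dplyr::select("trainee_id", "block_id", "role", "rotation", "n_eds", "n_srs",
                  "edv_duration", "edv_interval", "edv_total",
                  "srv_duration", "srv_interval", "srv_total") |>
    dplyr::arrange(.data$trainee_id, .data$block_id)
}

#' Exclude resident-blocks with zero self-reported shifts
#'
#' Paired SRV-vs-EDV analyses are only meaningful where the trainee logged
#' anything at all in the self-report system; blocks with `n_srs = 0` are
#' removed and an exclusion report (block and trainee counts with
#' percentages to one decimal) is returned alongside.
#'
#' @param tallies Resident-block tallies from [tally_blocks()].
#' @return A list with `eligible` (the retained tallies) and `report`
#'   (one-row tibble of exclusion bookkeeping).
#' @export
exclude_unlogged_blocks <- function(tallies) {
  unlogged <- tallies$n_srs == 0L
  eligible <- tallies[!unlogged, , drop = FALSE]
  all_trainees <- unique(tallies$trainee_id)
  eligible_trainees <- unique(eligible$trainee_id)
  n_blocks <- nrow(tallies)
  n_excl <- sum(unlogged)
  n_tr <- length(all_trainees)
  n_tr_excl <- n_tr - length(eligible_trainees)
  report <- tibble::tibble(
    n_blocks_total = n_blocks,
    n_blocks_excluded = n_excl,
    n_blocks_eligible = n_blocks - n_excl,
    pct_blocks_excluded = round(100 * n_excl / n_blocks, 1),
    pct_blocks_eligible = round(100 * (n_blocks - n_excl) / n_blocks, 1),
    n_trainees_total = n_tr,
    n_trainees_excluded = n_tr_excl,
    pct_trainees_excluded = round(100 * n_tr_excl / n_tr, 1)
  )
  list(eligible = eligible, report = report)
}

#' Paired block-level difference of self-reported and EHR-defined violations
#'
#' For every eligible resident-block computes `diff = srv_total -
#' edv_total` and classifies the block as UNDER (diff < 0: the trainee
#' self-reported fewer violations than the EHR shows), EQUAL, or OVER
#' (diff > 0).
#'
#' @param eligible_tallies Tallies restricted to blocks with any SRS (see
#'   [exclude_unlogged_blocks()]).
#' @return A list with `comparisons` (per-block diffs and classes),
#'   `summary` (counts and percentages of each class), and `histogram`
#'   (diff value, block count) ready for export.
#' @export
paired_difference <- function(eligible_tallies) {
  comparisons <- eligible_tallies |>
    dplyr::mutate(diff = .data$srv_total - .data$edv_total,
                  class = dplyr::case_when(.data$diff < 0 ~ "UNDER",
                                           .data$diff > 0 ~ "OVER",
                                           TRUE ~ "EQUAL"))
  n <- nrow(comparisons)
  n_under <- sum(comparisons$class == "UNDER")
  n_over <- sum(comparisons$class == "OVER")
  n_equal <- n - n_under - n_over
  summary <- tibble::tibble(
    n_blocks = n, n_under = n_under, n_over = n_over, n_equal = n_equal,
    pct_under = round(100 * n_under / n, 1),
    pct_over = round(100 * n_over / n, 1),
    pct_equal = round(100 * n_equal / n, 1)
  )
  histogram <- dplyr::count(comparisons, .data$diff, name = "count")
  list(comparisons = comparisons, summary = summary, histogram = histogram)
}

#' Violations per resident-block by role, with ANOVA and Tukey HSD
#'
#' Descriptive mean, SEM (sample sd / sqrt(n), n - 1 denominator) and block
#' count per role for the chosen source, followed by a one-way ANOVA of
#' total violations across roles and Tukey-adjusted pairwise comparisons.
#' Inference is skipped with a warning when fewer than two roles have at
#' least two blocks.
#'
#' @param tallies Resident-block tallies.
#' @param source `"EHR_DEFINED"` (EDV) or `"SELF_REPORTED"` (SRV).
#' @return A list with `summary` (role, n_blocks, mean, sem), `anova`
#'   (f, p, df), and `tukey` (pairwise table), the latter two `NULL` when
#'   inference is skipped.
#' @export
role_summary <- function(tallies, source = c("EHR_DEFINED", "SELF_REPORTED")) {
  source <- match.arg(source)
  value <- if (source == "EHR_DEFINED") tallies$edv_total else tallies$srv_total
  d <- tibble::tibble(role = factor(tallies$role, levels = ROLES), value = value)
  d <- d[!is.na(d$role), , drop = FALSE]
  d$role <- droplevels(d$role)
  summary <- d |>
    dplyr::group_by(.data$role) |>
    dplyr::summarise(n_blocks = dplyr::n(),
                     mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  enough <- sum(summary$n_blocks >= 2L) >= 2L && nlevels(d$role) >= 2L
  if (!enough) {
    warning("role_summary: fewer than two roles with >= 2 blocks; inference skipped",
            call. = FALSE)
    return(list(summary = summary, anova = NULL, tukey = NULL))
  }
  fit <- stats::aov(value ~ role, data = d)
  av <- summary(fit)[[1L]]
  anova <- list(f = av[["F value"]][1L], p = av[["Pr(>F)"]][1L],
                df_between = av[["Df"]][1L], df_within = av[["Df"]][2L])
  tk <- stats::TukeyHSD(fit)$role
  tukey <- tibble::tibble(comparison = rownames(tk), diff = unname(tk[, "diff"]),
                          lwr = unname(tk[, "lwr"]), upr = unname(tk[, "upr"]),
                          p_adj = unname(tk[, "p adj"]))
  list(summary = summary, anova = anova, tukey = tukey)
}

#' Multivariable linear model of total violations per resident-block
#'
#' Reshapes eligible tallies to long form (one row per block x source) and
#' fits ordinary least squares: `total ~ source_SRV + role_SR_FLC +
#' role_SR_SUPRV`, i.e. the self-report indicator against the EHR-defined
#' reference, adjusted for role against the junior front-line reference. A
#' negative `source_SRV` coefficient quantifies systematic under-reporting
#' in violations per block.
#'
#' @param eligible_tallies Tallies restricted to blocks with any SRS.
#' @return A list with `coefficients` (term, estimate, std_error, t_value,
#'   p_value), `long` (the model frame), and `model` (the `lm` fit).
#' @export
fit_violation_model <- function(eligible_tallies) {
  long <- dplyr::bind_rows(
    dplyr::transmute(eligible_tallies, trainee_id = .data$trainee_id,
                     block_id = .data$block_id, role = .data$role,
                     source = "EDV", total = .data$edv_total),
    dplyr::transmute(eligible_tallies, trainee_id = .data$trainee_id,
                     block_id = .data$block_id, role = .data$role,
                     source = "SRV", total = .data$srv_total)
  )
  long$source_SRV <- as.integer(long$source == "SRV")
  long$role_SR_FLC <- as.integer(long$role == "SR_FLC")
  long$role_SR_SUPRV <- as.integer(long$role == "SR_SUPRV")
  X <- cbind(`(Intercept)` = 1, source_SRV = long$source_SRV,
             role_SR_FLC = long$role_SR_FLC, role_SR_SUPRV = long$role_SR_SUPRV)
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    aliased <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm(total ~ source_SRV + role_SR_FLC + role_SR_SUPRV, data = long)
  cf <- summary(fit)$coefficients
  coefficients <- tibble::tibble(
    term = rownames(cf), estimate = cf[, "Estimate"],
    std_error = cf[, "Std. Error"], t_value = cf[, "t value"],
    p_value = cf[, "Pr(>|t|)"]
  )
  list(coefficients = coefficients, long = long, model = fit)
}
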