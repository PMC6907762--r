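#' Build an academic-year block calendar
#'
#' Thirteen contiguous blocks by default: 28 days each, with an extra day
#' (29) on the first and last block so the year is covered end to end.
#'
#' @param start_date First day of block 1.
#' @param n_blocks Number of blocks.
#' @param interior_days,boundary_days Lengths of interior and first/last blocks.
#' @return A calendar tibble as from [read_block_calendar()].
#' @export
make_academic_calendar <- function(start_date = as.Date("2015-06-29"),
                                   n_blocks = 13L,
                                   interior_days = 28L, boundary_days = 29L) {
  stopifnot(n_blocks >= 1L)
  len <- rep(interior_days, n_blocks)
  len[c(1L, n_blocks)] <- boundary_days
  start <- start_date + cumsum(c(0L, len[-n_blocks]))
  tibble::tibble(block_id = sprintf("B%02d", seq_len(n_blocks)),
                 start_date = start, length_days = as.integer(len),
                 end_date = start + len)
}

#' Build a workstation directory with on-site and off-site stations
#'
#' @param n_onsite,n_offsite Station counts.
#' @return Directory tibble (`workstation_id`, `onsite`).
#' @export
generate_workstations <- function(n_onsite = 40L, n_offsite = 10L) {
  stopifnot(n_onsite >= 1L)
  tibble::tibble(
    workstation_id = c(sprintf("WS-H%03d", seq_len(n_onsite)),
                       if (n_offsite > 0L) sprintf("WS-R%03d", seq_len(n_offsite))),
    onsite = rep(c(TRUE, FALSE), c(n_onsite, n_offsite))
  )
}

# Rotation -> schedule template for the default simulated service lines.
default_templates <- function() {
  c(WARDS = "Q4_CALL", ICU = "Q4_CALL", NICU = "DAY_NIGHT", TEAM_DN = "DAY_NIGHT")
}

#' Scheduling and violation-seeding parameters
#'
#' Controls how true shifts are laid down on the two schedule templates and
#' how duty-hour violations are seeded into them. Duration violations arise
#' only on call slots: with probability `p_call_overage_by_role` a call runs
#' past the role's legal maximum by a lognormal excess (minutes), capped at
#' `overage_cap_minutes`; otherwise the call ends `call_slack_minutes` short
#' of the cap. Interval violations arise from early call-ins: with
#' probability `p_early_start_by_role` a shift is moved to start after only
#' a fraction (`early_rest_frac` range) of the required rest.
#'
#' The defaults are calibration inputs chosen to give per-block violation
#' rates of the magnitude seen in large inpatient training programs
#' (roughly 0.6 / 2.3 / 1.4 violations per block for junior front-line,
#' senior front-line, and supervisory roles).
#'
#' @param p_call_overage_by_role Named per-role probability a call slot
#'   exceeds the role maximum.
#' @param overage_meanlog,overage_sdlog Lognormal excess parameters (the
#'   defaults give median ~36 min with quartiles ~16 and ~70 min).
#' @param overage_cap_minutes Upper clamp on the excess.
#' @param call_slack_minutes How far a non-overrunning call ends short of
#'   the cap.
#' @param p_early_start_by_role Named per-role probability of an early
#'   call-in on an eligible slot.
#' @param early_rest_frac Range of realized/required rest for early
#'   call-ins; the lower bound must keep realized rest above the
#'   segmentation gap threshold so true shifts remain separable.
#' @return An object of class `schedule_params`.
#' @export
schedule_params <- function(
    p_call_overage_by_role = c(JR_FLC = 0.12, SR_FLC = 0.42, SR_SUPRV = 0.25),
    overage_meanlog = log(36.3), overage_sdlog = 1.084,
    overage_cap_minutes = 240, call_slack_minutes = 60,
    p_early_start_by_role = c(JR_FLC = 0.010, SR_FLC = 0.006, SR_SUPRV = 0.006),
    early_rest_frac = c(0.65, 0.92)) {
  stopifnot(all(p_call_overage_by_role >= 0 & p_call_overage_by_role <= 1),
            all(p_early_start_by_role >= 0 & p_early_start_by_role <= 1),
            overage_cap_minutes > 0, call_slack_minutes >= 0,
            length(early_rest_frac) == 2L,
            early_rest_frac[1] > 0, early_rest_frac[2] < 1,
            early_rest_frac[1] < early_rest_frac[2])
  structure(list(p_call_overage_by_role = p_call_overage_by_role,
                 overage_meanlog = overage_meanlog, overage_sdlog = overage_sdlog,
                 overage_cap_minutes = overage_cap_minutes,
                 call_slack_minutes = call_slack_minutes,
                 p_early_start_by_role = p_early_start_by_role,
                 early_rest_frac = early_rest_frac),
            class = "schedule_params")
}

#' Deterministic shift slots of a schedule template
#'
#' `Q4_CALL`: an extended call slot every fourth day (08:00), interleaved
#' with 10-hour day shifts — 17 slots on a 28-day block. `DAY_NIGHT`: 12-hour
#' shifts (07:00 days for the first half of the block, 19:00 nights for the
#' second) with one day off per week — 23 slots on a 28-day block. Both
#' templates leave the end of the block clear so consecutive blocks of one
#' trainee can never overlap.
#'
#' @param template `"Q4_CALL"` or `"DAY_NIGHT"`.
#' @param length_days Block length (28 or 29 in the default calendar).
#' @return A tibble with `day` (0-based), `start_min` (minutes after local
#'   midnight), `base_duration_minutes` (`NA` for call slots, whose length
#'   is role-dependent), `is_call`.
#' @export
schedule_template_slots <- function(template = c("Q4_CALL", "DAY_NIGHT"),
                                    length_days) {
  template <- match.arg(template)
  stopifnot(length_days >= 28L)
  if (template == "Q4_CALL") {
    call_days <- seq(0L, length_days - 4L, by = 4L)
    day_days <- setdiff(c(seq(2L, length_days - 2L, by = 4L), c(3L, 7L, 11L),
                          if (length_days >= 29L) 27L), call_days)
    slots <- dplyr::bind_rows(
      tibble::tibble(day = call_days, start_min = 480, base_duration_minutes = NA_real_,
                     is_call = TRUE),
      tibble::tibble(day = as.integer(day_days), start_min = 480,
                     base_duration_minutes = 600, is_call = FALSE)
    )
  } else {
    off <- unique(c(which(seq(0L, length_days - 1L) %% 7L == 6L) - 1L, 26L,
                    length_days - 1L))
    work <- setdiff(seq(0L, length_days - 1L), off)
    slots <- tibble::tibble(
      day = work,
      start_min = ifelse(work < 14L, 420, 1140),
      base_duration_minutes = 720,
      is_call = FALSE
    )
  }
  dplyr::arrange(slots, .data$day, .data$start_min)
}

#' Generate a simulated trainee roster
#'
#' Each trainee works every block of the calendar. Role category is drawn
#' per trainee (junior vs senior, from `role_mix["JR_FLC"]`); juniors are
#' PGY-1 and always `JR_FLC`, seniors (PGY 2-4) are assigned per block to
#' `SR_FLC` or `SR_SUPRV` in proportion to the remaining mix, so the
#' block-level role proportions match `role_mix` up to multinomial noise.
#' Rotations are drawn per block, with role-specific odds of landing on a
#' q4-call versus day-night service.
#'
#' @param n_trainees Number of trainees.
#' @param role_mix Named proportions for `JR_FLC`, `SR_FLC`, `SR_SUPRV`
#'   (must be non-negative and sum to 1).
#' @param calendar Block calendar.
#' @param seed Integer seed (set if non-`NULL`).
#' @param templates Named rotation -> template map.
#' @param p_q4_by_role Named per-role probability of a q4-call rotation.
#' @return Roster tibble (`trainee_id, pgy, block_id, role, rotation`).
#' @export
generate_cohort <- function(n_trainees, role_mix = c(JR_FLC = 0.440, SR_FLC = 0.396,
                                                     SR_SUPRV = 0.164),
                            calendar = make_academic_calendar(), seed = NULL,
                            templates = default_templates(),
                            p_q4_by_role = c(JR_FLC = 0.50, SR_FLC = 0.75,
                                             SR_SUPRV = 0.75)) {
  if (!all(ROLES %in% names(role_mix)) || any(role_mix < 0) ||
      abs(sum(role_mix) - 1) > 1e-6) {
    stop("role_mix must be named proportions over JR_FLC/SR_FLC/SR_SUPRV summing to 1",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  trainee_id <- sprintf("T%04d", seq_len(n_trainees))
  junior <- stats::runif(n_trainees) < role_mix[["JR_FLC"]]
  pgy <- ifelse(junior, 1L,
                sample(2:4, n_trainees, replace = TRUE, prob = c(0.757, 0.236, 0.007)))
  roster <- tidyr::expand_grid(trainee_id = trainee_id, block_id = calendar$block_id)
  roster$pgy <- pgy[match(roster$trainee_id, trainee_id)]
  is_jr <- roster$pgy == 1L
  p_suprv <- role_mix[["SR_SUPRV"]] / (role_mix[["SR_FLC"]] + role_mix[["SR_SUPRV"]])
  roster$role <- ifelse(is_jr, "JR_FLC",
                        ifelse(stats::runif(nrow(roster)) < p_suprv,
                               "SR_SUPRV", "SR_FLC"))
  q4_rot <- names(templates)[templates == "Q4_CALL"]
  dn_rot <- names(templates)[templates == "DAY_NIGHT"]
  on_q4 <- stats::runif(nrow(roster)) < unname(p_q4_by_role[roster$role])
  roster$rotation <- ifelse(on_q4,
                            sample(q4_rot, nrow(roster), replace = TRUE),
                            sample(dn_rot, nrow(roster), replace = TRUE))
  dplyr::select(roster, "trainee_id", "pgy", "block_id", "role", "rotation")
}

#' Generate ground-truth shifts for a roster
#'
#' Lays template slots onto the calendar in the reference timezone, sizes
#' call slots by role (the cap minus `call_slack_minutes` when legal, the
#' cap plus a lognormal excess when seeded as a duration violation), and
#' applies early call-ins to seed interval violations. Overage is restricted
#' to call slots — which are always followed by at least two clear days — so
#' an extended shift can never collide with, or force inadequate rest
#' before, its successor; early call-ins keep at least
#' `early_rest_frac[1] * required rest` between shifts.
#'
#' @param roster Roster tibble.
#' @param calendar Block calendar.
#' @param sched A [schedule_params()] object.
#' @param rules A [duty_hour_rules()] object (role caps size the call slots).
#' @param templates Named rotation -> template map.
#' @param seed Integer seed.
#' @param tz Reference timezone for slot wall-clock times.
#' @return A shift tibble (`source = "EHR_DEFINED"`, i.e. directly usable as
#'   the recovery target for inferred shifts) annotated with `block_id`,
#'   `role`, `rotation`, a stable `shift_id`, and truth labels `is_call`,
#'   `extended` (duration violation seeded), `early_start` (interval
#'   violation seeded).
#' @export
generate_true_shifts <- function(roster, calendar, sched = schedule_params(),
                                 rules = duty_hour_rules(),
                                 templates = default_templates(), seed = NULL,
                                 tz = "America/New_York") {
  if (!is.null(seed)) set.seed(seed)
  missing_t <- setdiff(unique(roster$rotation), names(templates))
  if (length(missing_t) > 0L) {
    stop(sprintf("no schedule template for rotation(s): %s",
                 paste(missing_t, collapse = ", ")), call. = FALSE)
  }
  rb <- dplyr::inner_join(roster, calendar[c("block_id", "start_date", "length_days")],
                          by = "block_id")
  rb$template <- unname(templates[rb$rotation])
  slot_sets <- unique(rb[c("template", "length_days")])
  slots_all <- dplyr::bind_rows(lapply(seq_len(nrow(slot_sets)), function(i) {
    s <- schedule_template_slots(slot_sets$template[i], slot_sets$length_days[i])
    s$template <- slot_sets$template[i]
    s$length_days <- slot_sets$length_days[i]
    s
  }))
  d <- dplyr::inner_join(rb, slots_all, by = c("template", "length_days"),
                         relationship = "many-to-many")

  # Local wall-clock slot start: minutes after local midnight of the slot day.
  d$start <- as.POSIXct(paste(d$start_date + d$day, "00:00:00"), tz = tz) +
    d$start_min * 60

  cap <- unname(rules$max_duration_by_role[d$role])
  d$duration_minutes <- ifelse(d$is_call, cap - sched$call_slack_minutes,
                               d$base_duration_minutes)

  # Seed duration violations on call slots.
  p_over <- unname(sched$p_call_overage_by_role[d$role])
  d$extended <- d$is_call & stats::runif(nrow(d)) < p_over
  excess <- pmin(stats::rlnorm(nrow(d), sched$overage_meanlog, sched$overage_sdlog),
                 sched$overage_cap_minutes)
  d$duration_minutes[d$extended] <- cap[d$extended] + excess[d$extended]
  # Whole-second durations so shifts survive CSV round-trips exactly.
  dur_sec <- round(d$duration_minutes * 60)
  d$end <- d$start + dur_sec

  # Seed interval violations: early call-ins relative to the previous shift
  # in the same block, skipping any slot adjacent to an extended call.
  d <- dplyr::arrange(d, .data$trainee_id, .data$start)
  prev_end <- dplyr::lag(d$end)
  prev_dur <- dplyr::lag(d$duration_minutes)
  prev_ext <- dplyr::lag(d$extended)
  same <- !is.na(prev_end) & dplyr::lag(d$trainee_id) == d$trainee_id &
    dplyr::lag(d$block_id) == d$block_id
  p_early <- unname(sched$p_early_start_by_role[d$role])
  cand <- same & !d$extended & !is.na(prev_ext) & !prev_ext &
    stats::runif(nrow(d)) < p_early
  f <- stats::runif(nrow(d), sched$early_rest_frac[1], sched$early_rest_frac[2])
  req <- rep(NA_real_, nrow(d))
  has_prev <- !is.na(prev_dur)
  req[has_prev] <- required_rest(prev_dur[has_prev], rules)
  new_start <- prev_end + round(f * req * 60)
  apply_early <- cand & !is.na(new_start) & new_start < d$start
  d$early_start <- apply_early
  d$start[apply_early] <- new_start[apply_early]
  d$end[apply_early] <- d$start[apply_early] + dur_sec[apply_early]

  out <- tibble::tibble(
    shift_id = sprintf("S%06d", seq_len(nrow(d))),
    trainee_id = d$trainee_id,
    start = lubridate::with_tz(d$start, "UTC"),
    end = lubridate::with_tz(d$end, "UTC"),
    source = "EHR_DEFINED",
    duration_minutes = mins_between(d$start, d$end),
    block_id = d$block_id, role = d$role, rotation = d$rotation,
    is_call = d$is_call, extended = d$extended, early_start = d$early_start
  )
  check_shift_tbl(out, "generated true shifts (template overlap)")
  out
}

#' Event-process parameters for the simulated access log
#'
#' Within a shift, events follow a homogeneous Poisson process (mean gap
#' `mean_gap` minutes) with gaps clamped at `max_gap`; for shift-recovery
#' experiments `max_gap` must stay below the segmentation
#' `long_gap_threshold`. The first event falls within `first_event_lag`
#' minutes of the true start and the last within `last_event_lead` of the
#' true end (both uniform; 0 means events span the shift exactly).
#' Off-site noise events occur at `offsite_rate_per_day` per trainee-day.
#'
#' @param mean_gap,max_gap Intra-shift gap mean and clamp, minutes.
#' @param first_event_lag,last_event_lead Uniform bounds, minutes.
#' @param offsite_rate_per_day Off-site noise rate (events/trainee/day).
#' @return An object of class `event_process_params`.
#' @export
event_process_params <- function(mean_gap = 30, max_gap = 240,
                                 first_event_lag = 0, last_event_lead = 0,
                                 offsite_rate_per_day = 0) {
  stopifnot(mean_gap > 0, max_gap > mean_gap, first_event_lag >= 0,
            last_event_lead >= 0, offsite_rate_per_day >= 0)
  structure(list(mean_gap = mean_gap, max_gap = max_gap,
                 first_event_lag = first_event_lag,
                 last_event_lead = last_event_lead,
                 offsite_rate_per_day = offsite_rate_per_day),
            class = "event_process_params")
}

#' Simulate an EHR access log over ground-truth shifts
#'
#' Every true shift produces at least two events (one at start + lag, one at
#' end - lead) with clamped-exponential gaps in between, on randomly chosen
#' on-site workstations; optional off-site noise events are scattered
#' uniformly over the study span on off-site workstations. Timestamps are
#' whole seconds.
#'
#' @param true_shifts Output of [generate_true_shifts()].
#' @param event_params An [event_process_params()] object.
#' @param workstations Workstation directory.
#' @param seed Integer seed.
#' @return An access-log tibble (`trainee_id, timestamp, workstation_id,
#'   event_code`) sorted by trainee and time.
#' @export
generate_events <- function(true_shifts, event_params = event_process_params(),
                            workstations = generate_workstations(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ep <- event_params
  onsite_ids <- workstations$workstation_id[workstations$onsite]
  offsite_ids <- workstations$workstation_id[!workstations$onsite]
  stopifnot(length(onsite_ids) > 0L)
  n_shift <- nrow(true_shifts)
  dur <- true_shifts$duration_minutes
  lag <- pmin(stats::runif(n_shift, 0, ep$first_event_lag), dur / 3)
  lead <- pmin(stats::runif(n_shift, 0, ep$last_event_lead), dur / 3)
  span <- dur - lag - lead

  # Clamped-exponential inner gaps, drawn in one batch with generous margin;
  # the rare shift whose draws fall short is regenerated on a slow path so
  # no inner gap (including the one to the closing event) exceeds max_gap.
  n_draw <- pmax(ceiling(span / ep$mean_gap * 2.2) + 10L, 2L)
  gaps <- pmin(stats::rexp(sum(n_draw), rate = 1 / ep$mean_gap), ep$max_gap)
  idx <- rep.int(seq_len(n_shift), n_draw)
  cs <- cumsum(gaps)
  first_of <- cumsum(c(1L, n_draw[-n_shift]))
  base <- cs[first_of] - gaps[first_of]
  within <- cs - rep.int(base, n_draw)

  keep <- within < rep.int(span, n_draw)
  grp <- factor(idx, levels = seq_len(n_shift))
  kept <- split(within[keep], grp[keep])
  covered <- vapply(split(within, grp), max, numeric(1)) >= span
  offsets <- vector("list", n_shift)
  for (i in seq_len(n_shift)) {
    w <- kept[[i]]
    if (!covered[i]) {  # slow path: extend until the span is covered
      tail_at <- if (length(w)) max(w) else 0
      while (tail_at < span[i]) {
        g <- min(stats::rexp(1L, rate = 1 / ep$mean_gap), ep$max_gap)
        tail_at <- tail_at + g
        if (tail_at < span[i]) w <- c(w, tail_at)
      }
    }
    offsets[[i]] <- c(0, w, span[i])
  }
  n_ev <- lengths(offsets)
  ev_time <- true_shifts$start[rep.int(seq_len(n_shift), n_ev)] +
    round((rep.int(lag, n_ev) + unlist(offsets)) * 60)
  events <- tibble::tibble(
    trainee_id = true_shifts$trainee_id[rep.int(seq_len(n_shift), n_ev)],
    timestamp = ev_time,
    workstation_id = sample(onsite_ids, sum(n_ev), replace = TRUE),
    event_code = sample(c("LOGIN", "CHART_OPEN", "ORDER_ENTRY", "NOTE_EDIT"),
                        sum(n_ev), replace = TRUE)
  )

  if (ep$offsite_rate_per_day > 0 && length(offsite_ids) > 0L) {
    trainees <- unique(true_shifts$trainee_id)
    span_days <- as.numeric(difftime(max(true_shifts$end), min(true_shifts$start),
                                     units = "days"))
    n_noise <- stats::rpois(length(trainees), ep$offsite_rate_per_day * span_days)
    noise <- tibble::tibble(
      trainee_id = rep.int(trainees, n_noise),
      timestamp = min(true_shifts$start) +
        round(stats::runif(sum(n_noise), 0, span_days * 86400)),
      workstation_id = sample(offsite_ids, sum(n_noise), replace = TRUE),
      event_code = "REMOTE_ACCESS"
    )
    events <- dplyr::bind_rows(events, noise)
  }
  dplyr::arrange(events, .data$trainee_id, .data$timestamp)
}

#' Self-reporting behavior model
#'
#' Mechanistic model of biased duty-hour logging: some trainees never log
#' at all (`p_trainee_unlogged` — non-logging is strongly trainee-correlated
#' in practice, so whole-year non-reporters dominate the excluded blocks),
#' further whole blocks may go unlogged (`p_block_unlogged`, conditional on
#' the trainee being a reporter; the defaults give a marginal unlogged-block
#' rate of about 0.17 + 0.83 x 0.06 = 0.22), individual shifts may be omitted
#' (`p_shift_omit`), shifts that exceed the role's legal maximum may be
#' reported as ending exactly at the maximum (`p_truncate_at_limit` —
#' erasing the violation from the self-report), and reported endpoints get
#' Gaussian jitter and optional rounding, applied last. Each mechanism is
#' independently switchable; [zero_reporting_behavior()] turns them all off,
#' making self-reports identical to the true shifts.
#'
#' @param p_trainee_unlogged Probability a trainee logs nothing all year.
#' @param p_block_unlogged Probability a reporter's resident-block logs
#'   nothing.
#' @param p_shift_omit Per-shift omission probability.
#' @param p_truncate_at_limit Probability an over-limit shift is reported at
#'   the limit.
#' @param round_minutes Rounding granularity for reported endpoints (0 = none).
#' @param jitter_sd_minutes SD of endpoint jitter (0 = none).
#' @return An object of class `reporting_behavior`.
#' @export
reporting_behavior <- function(p_trainee_unlogged = 0.17,
                               p_block_unlogged = 0.06, p_shift_omit = 0.03,
                               p_truncate_at_limit = 0.70,
                               round_minutes = 0, jitter_sd_minutes = 10) {
  probs <- c(p_trainee_unlogged, p_block_unlogged, p_shift_omit, p_truncate_at_limit)
  stopifnot(all(probs >= 0 & probs <= 1), round_minutes >= 0, jitter_sd_minutes >= 0)
  structure(list(p_trainee_unlogged = p_trainee_unlogged,
                 p_block_unlogged = p_block_unlogged, p_shift_omit = p_shift_omit,
                 p_truncate_at_limit = p_truncate_at_limit,
                 round_minutes = round_minutes,
                 jitter_sd_minutes = jitter_sd_minutes),
            class = "reporting_behavior")
}

#' @rdname reporting_behavior
#' @export
zero_reporting_behavior <- function() {
  reporting_behavior(p_trainee_unlogged = 0, p_block_unlogged = 0,
                     p_shift_omit = 0, p_truncate_at_limit = 0,
                     round_minutes = 0, jitter_sd_minutes = 0)
}

#' Simulate biased self-reports from ground-truth shifts
#'
#' @param true_shifts Output of [generate_true_shifts()].
#' @param behavior A [reporting_behavior()] object.
#' @param rules A [duty_hour_rules()] object (role caps define truncation).
#' @param seed Integer seed.
#' @return A list: `self_reports` — a shift tibble (`source =
#'   "SELF_REPORTED"`) keeping the block/role/rotation annotation; and
#'   `provenance` — one row per true shift recording every transformation
#'   (`block_unlogged`, `omitted`, `truncated`, `reported`).
#' @export
generate_self_reports <- function(true_shifts, behavior = reporting_behavior(),
                                  rules = duty_hour_rules(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- true_shifts
  trainees <- unique(d$trainee_id)
  nonreporter <- trainees[stats::runif(length(trainees)) < behavior$p_trainee_unlogged]
  blocks <- unique(d[c("trainee_id", "block_id")])
  blocks$unlogged <- blocks$trainee_id %in% nonreporter |
    stats::runif(nrow(blocks)) < behavior$p_block_unlogged
  d <- dplyr::left_join(d, blocks, by = c("trainee_id", "block_id"))
  d$omitted <- !d$unlogged & stats::runif(nrow(d)) < behavior$p_shift_omit
  cap <- unname(rules$max_duration_by_role[d$role])
  over <- d$duration_minutes > cap
  d$truncated <- !d$unlogged & !d$omitted & over &
    stats::runif(nrow(d)) < behavior$p_truncate_at_limit

  rep_start <- d$start
  rep_end <- d$end
  rep_end[d$truncated] <- rep_start[d$truncated] + cap[d$truncated] * 60
  if (behavior$jitter_sd_minutes > 0) {
    rep_start <- rep_start + round(stats::rnorm(nrow(d), 0, behavior$jitter_sd_minutes) * 60)
    rep_end <- rep_end + round(stats::rnorm(nrow(d), 0, behavior$jitter_sd_minutes) * 60)
    flip <- rep_end <= rep_start
    rep_end[flip] <- rep_start[flip] + 60
  }
  if (behavior$round_minutes > 0) {
    g <- behavior$round_minutes * 60
    rep_start <- as.POSIXct(round(as.numeric(rep_start) / g) * g,
                            origin = "1970-01-01", tz = "UTC")
    rep_end <- as.POSIXct(round(as.numeric(rep_end) / g) * g,
                          origin = "1970-01-01", tz = "UTC")
    flip <- rep_end <= rep_start
    rep_end[flip] <- rep_start[flip] + g
  }

  reported <- !d$unlogged & !d$omitted
  provenance <- tibble::tibble(
    shift_id = d$shift_id, trainee_id = d$trainee_id, block_id = d$block_id,
    block_unlogged = d$unlogged, omitted = d$omitted, truncated = d$truncated,
    reported = reported
  )
  srs <- tibble::tibble(
    trainee_id = d$trainee_id[reported],
    start = rep_start[reported], end = rep_end[reported],
    source = "SELF_REPORTED",
    duration_minutes = mins_between(rep_start[reported], rep_end[reported]),
    block_id = d$block_id[reported], role = d$role[reported],
    rotation = d$rotation[reported]
  ) |>
    dplyr::arrange(.data$trainee_id, .data$start)
  check_shift_tbl(srs, "simulated self reports")
  list(self_reports = srs, provenance = provenance)
}

#' Oracle violations over the ground-truth shifts
#'
#' Applies the duty-hour rule engine to the true (generated) shifts; serves
#' as the recovery target for end-to-end tests of the event -> inference ->
#' violation pipeline.
#'
#' @param true_shifts Output of [generate_true_shifts()].
#' @param rules A [duty_hour_rules()] object.
#' @return Violation tibble.
#' @export
ground_truth_violations <- function(true_shifts, rules = duty_hour_rules()) {
  detect_violations(true_shifts, rules)
}

#' Run the full simulator: roster, shifts, events, self-reports, truth
#'
#' One call producing every input the pipeline ingests plus the ground-truth
#' labels, fully determined by `seed`. Sub-generators receive consecutive
#' derived seeds so each stage is independently reproducible.
#'
#' @param n_trainees Number of trainees.
#' @param seed Master integer seed.
#' @param calendar Block calendar.
#' @param role_mix,behavior,sched,event_params,rules,templates,workstations
#'   Stage parameter objects (see the respective constructors).
#' @param generate_event_log If `FALSE`, skip the (comparatively expensive)
#'   access-log simulation; `events` is then `NULL`.
#' @param tz Reference timezone.
#' @return A list: `roster`, `calendar`, `workstations`, `true_shifts`,
#'   `events`, `self_reports`, `provenance`, `true_violations`.
#' @export
simulate_study <- function(n_trainees = 60L, seed = 1L,
                           calendar = make_academic_calendar(),
                           role_mix = c(JR_FLC = 0.440, SR_FLC = 0.396,
                                        SR_SUPRV = 0.164),
                           behavior = reporting_behavior(),
                           sched = schedule_params(),
                           event_params = event_process_params(),
                           rules = duty_hour_rules(),
                           templates = default_templates(),
                           workstations = generate_workstations(),
                           generate_event_log = TRUE,
                           tz = "America/New_York") {
  roster <- generate_cohort(n_trainees, role_mix, calendar, seed = seed,
                            templates = templates)
  true_shifts <- generate_true_shifts(roster, calendar, sched, rules, templates,
                                      seed = seed + 1000000L, tz = tz)
  events <- if (generate_event_log) {
    generate_events(true_shifts, event_params, workstations, seed = seed + 2000000L)
  }
  sr <- generate_self_reports(true_shifts, behavior, rules, seed = seed + 3000000L)
  list(roster = roster, calendar = calendar, workstations = workstations,
       true_shifts = true_shifts, events = events,
       self_reports = sr$self_reports, provenance = sr$provenance,
       true_violations = ground_truth_violations(true_shifts, rules))
}

#' Write the simulated study to the five ingest CSVs plus truth labels
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_simulated_inputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    access_log = file.path(dir, "access_log.csv"),
    workstations = file.path(dir, "workstations.csv"),
    roster = file.path(dir, "roster.csv"),
    blocks = file.path(dir, "blocks.csv"),
    self_reports = file.path(dir, "self_reports.csv"),
    true_shifts = file.path(dir, "true_shifts.csv"),
    true_violations = file.path(dir, "true_violations.csv"),
    report_provenance = file.path(dir, "report_provenance.csv")
  )
  if (!is.null(sim$events)) {
    ev <- sim$events
    ev$timestamp <- fmt_utc(ev$timestamp)
    readr::write_csv(ev, paths[["access_log"]])
  }
  ws <- sim$workstations
  ws$onsite <- as.integer(ws$onsite)
  readr::write_csv(ws, paths[["workstations"]])
  readr::write_csv(sim$roster, paths[["roster"]])
  readr::write_csv(sim$calendar[c("block_id", "start_date", "length_days")],
                   paths[["blocks"]])
  readr::write_csv(tibble::tibble(trainee_id = sim$self_reports$trainee_id,
                                  start = fmt_utc(sim$self_reports$start),
                                  end = fmt_utc(sim$self_reports$end)),
                   paths[["self_reports"]])
  ts <- sim$true_shifts
  ts$start <- fmt_utc(ts$start)
  ts$end <- fmt_utc(ts$end)
  readr::write_csv(ts, paths[["true_shifts"]])
  tv <- sim$true_violations
  tv$shift_start <- fmt_utc(tv$shift_start)
  tv$shift_end <- fmt_utc(tv$shift_end)
  readr::write_csv(tv, paths[["true_violations"]])
  readr::write_csv(sim$provenance, paths[["report_provenance"]])
  invisible(paths)
}
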