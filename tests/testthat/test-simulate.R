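small_cal <- make_academic_calendar(as.Date("2015-06-29"), n_blocks = 2L)

test_that("every generator is deterministic under a fixed seed", {
  a <- simulate_study(n_trainees = 4, seed = 5, calendar = small_cal)
  b <- simulate_study(n_trainees = 4, seed = 5, calendar = small_cal)
  expect_identical(a$roster, b$roster)
  expect_identical(a$true_shifts, b$true_shifts)
  expect_identical(a$events, b$events)
  expect_identical(a$self_reports, b$self_reports)
  c <- simulate_study(n_trainees = 4, seed = 6, calendar = small_cal)
  expect_false(identical(a$true_shifts, c$true_shifts))
})

test_that("cohort role mix is honored up to multinomial noise", {
  one_block <- make_academic_calendar(n_blocks = 1L)
  all_jr <- generate_cohort(50, c(JR_FLC = 1, SR_FLC = 0, SR_SUPRV = 0),
                            one_block, seed = 1)
  expect_true(all(all_jr$role == "JR_FLC"))
  expect_true(all(all_jr$pgy == 1L))
  mix <- c(JR_FLC = 0.44, SR_FLC = 0.40, SR_SUPRV = 0.16)
  big <- generate_cohort(1000, mix, one_block, seed = 2)
  props <- table(big$role)[names(mix)] / nrow(big)
  expect_true(all(abs(props - mix) < 0.04))
  expect_error(generate_cohort(10, c(JR_FLC = 0.6, SR_FLC = 0.6, SR_SUPRV = 0.1),
                               one_block), "role_mix")
})

test_that("schedule templates produce the expected deterministic slot counts", {
  expect_equal(nrow(schedule_template_slots("Q4_CALL", 28L)), 17L)
  expect_equal(nrow(schedule_template_slots("DAY_NIGHT", 28L)), 23L)
  expect_equal(nrow(schedule_template_slots("Q4_CALL", 29L)), 18L)
  expect_equal(nrow(schedule_template_slots("DAY_NIGHT", 29L)), 23L)
  q4 <- schedule_template_slots("Q4_CALL", 28L)
  expect_equal(sum(q4$is_call), 7L)
  expect_equal(diff(q4$day[q4$is_call]), rep(4L, 6L))
})

test_that("true shifts per block equal the template slot count and never overlap", {
  roster <- generate_cohort(6, calendar = small_cal, seed = 3)
  ts <- generate_true_shifts(roster, small_cal, seed = 4)
  counts <- dplyr::count(ts, trainee_id, block_id, rotation)
  tmpl <- default_templates()
  for (i in seq_len(nrow(counts))) {
    len <- small_cal$length_days[match(counts$block_id[i], small_cal$block_id)]
    expect_equal(counts$n[i],
                 nrow(schedule_template_slots(tmpl[[counts$rotation[i]]], len)))
  }
  # non-overlap within trainee across the whole year
  by_t <- split(ts, ts$trainee_id)
  for (d in by_t) {
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})

test_that("degenerate overage seeds no senior duration violations", {
  roster <- generate_cohort(6, calendar = small_cal, seed = 3)
  quiet <- schedule_params(p_call_overage_by_role = c(JR_FLC = 0, SR_FLC = 0,
                                                      SR_SUPRV = 0))
  ts <- generate_true_shifts(roster, small_cal, sched = quiet, seed = 4)
  v <- ground_truth_violations(ts)
  expect_equal(sum(v$type == "DURATION"), 0L)
})

test_that("event streams cover every shift and respect the gap cap", {
  roster <- generate_cohort(3, calendar = small_cal, seed = 3)
  ts <- generate_true_shifts(roster, small_cal, seed = 4)
  ep <- event_process_params(mean_gap = 30, max_gap = 240, offsite_rate_per_day = 0)
  ev <- generate_events(ts, ep, generate_workstations(), seed = 5)
  expect_true(all(grepl("^WS-H", ev$workstation_id)))  # no off-site noise
  # zero lag/lead: first and last events sit exactly on the true boundaries
  for (i in sample(nrow(ts), 20)) {
    sub <- ev$timestamp[ev$trainee_id == ts$trainee_id[i] &
                          ev$timestamp >= ts$start[i] & ev$timestamp <= ts$end[i]]
    expect_gte(length(sub), 2L)
    expect_equal(min(sub), ts$start[i])
    expect_equal(max(sub), ts$end[i])
    expect_true(all(diff(as.numeric(sub)) / 60 <= 240))
  }
  # Poisson sanity: a 720-min shift at mean gap 30 gives ~24 events
  long_one <- ts[ts$duration_minutes == 720, ][1, ]
  n_ev <- sum(ev$trainee_id == long_one$trainee_id &
                ev$timestamp >= long_one$start & ev$timestamp <= long_one$end)
  expect_gt(n_ev, 24 - 3 * sqrt(24))
  expect_lt(n_ev, 24 + 3 * sqrt(24) + 2)
  # off-site noise lands on off-site stations only
  ev2 <- generate_events(ts, event_process_params(offsite_rate_per_day = 0.5),
                         generate_workstations(), seed = 6)
  noise <- ev2[ev2$event_code == "REMOTE_ACCESS", ]
  expect_gt(nrow(noise), 0L)
  expect_true(all(grepl("^WS-R", noise$workstation_id)))
})

test_that("an all-zero behavior model reports the truth verbatim", {
  roster <- generate_cohort(4, calendar = small_cal, seed = 3)
  ts <- generate_true_shifts(roster, small_cal, seed = 4)
  sr <- generate_self_reports(ts, zero_reporting_behavior(), seed = 5)
  expect_equal(nrow(sr$self_reports), nrow(ts))
  truth <- dplyr::arrange(ts, trainee_id, start)
  expect_equal(sr$self_reports$start, truth$start)
  expect_equal(sr$self_reports$end, truth$end)
  expect_true(all(sr$provenance$reported))
})

test_that("forced truncation erases self-reported duration violations", {
  roster <- generate_cohort(8, calendar = small_cal, seed = 3)
  hot <- schedule_params(p_call_overage_by_role = c(JR_FLC = 0.5, SR_FLC = 0.5,
                                                    SR_SUPRV = 0.5))
  ts <- generate_true_shifts(roster, small_cal, sched = hot, seed = 4)
  edv <- ground_truth_violations(ts)
  expect_gt(sum(edv$type == "DURATION"), 0L)
  trunc <- reporting_behavior(p_trainee_unlogged = 0, p_block_unlogged = 0,
                              p_shift_omit = 0, p_truncate_at_limit = 1,
                              jitter_sd_minutes = 0)
  sr <- generate_self_reports(ts, trunc, seed = 5)
  srv <- detect_violations(sr$self_reports)
  expect_equal(sum(srv$type == "DURATION"), 0L)
  expect_true(any(sr$provenance$truncated))
})

test_that("block-level non-logging matches its binomial rate", {
  cal13 <- make_academic_calendar()
  roster <- generate_cohort(77, calendar = cal13, seed = 7)  # 1001 blocks
  ts <- generate_true_shifts(roster, cal13, seed = 8)
  beh <- reporting_behavior(p_trainee_unlogged = 0, p_block_unlogged = 0.22,
                            jitter_sd_minutes = 0)
  sr <- generate_self_reports(ts, beh, seed = 9)
  unlogged <- sr$provenance |>
    dplyr::distinct(trainee_id, block_id, block_unlogged) |>
    dplyr::summarise(n = sum(block_unlogged))
  expect_gt(unlogged$n, 0.22 * 1001 - 40)
  expect_lt(unlogged$n, 0.22 * 1001 + 40)
})

test_that("an engineered 7-hour rest gap yields exactly one interval violation", {
  shifts <- mk_shifts("T1", c(0, 720 + 420, 3000), c(720, 720 + 420 + 600, 3600))
  shifts$role <- "JR_FLC"
  v <- ground_truth_violations(shifts)
  expect_equal(nrow(v), 1L)
  expect_equal(v$type, "INTERVAL")
  expect_equal(v$magnitude_minutes, 60)
})

test_that("simulated inputs round-trip through the ingest readers", {
  sim <- simulate_study(n_trainees = 3, seed = 11, calendar = small_cal)
  dir <- tempfile("sim")
  write_simulated_inputs(sim, dir)
  ev <- suppressMessages(read_access_log(file.path(dir, "access_log.csv")))
  expect_equal(nrow(ev), nrow(dplyr::distinct(sim$events)))
  expect_equal(ev$timestamp, dplyr::distinct(sim$events)$timestamp)
  ws <- read_workstations(file.path(dir, "workstations.csv"))
  expect_identical(ws, sim$workstations)
  ro <- read_roster(file.path(dir, "roster.csv"))
  expect_identical(ro, sim$roster)
  calb <- read_block_calendar(file.path(dir, "blocks.csv"))
  expect_equal(calb$start_date, sim$calendar$start_date)
  srs <- read_self_reports(file.path(dir, "self_reports.csv"))
  expect_equal(srs$start, sim$self_reports$start)
  expect_equal(srs$end, sim$self_reports$end)
})
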