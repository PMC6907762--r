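cal <- make_academic_calendar(as.Date("2015-06-29"))
roster1 <- tibble::tibble(trainee_id = "T1", pgy = 1L, block_id = cal$block_id,
                          role = "JR_FLC", rotation = "WARDS")

utc_shift <- function(trainee, start_chr, dur_min, source = "EHR_DEFINED") {
  start <- as.POSIXct(start_chr, tz = "UTC")
  tibble::tibble(trainee_id = trainee, start = start, end = start + dur_min * 60,
                 source = source, duration_minutes = dur_min)
}

test_that("shifts belong to the block containing their start instant", {
  # 23:00 UTC on block 1's last day (2015-07-27), running into block 2
  late <- utc_shift("T1", "2015-07-27 23:00:00", 600)
  a <- assign_blocks(late, cal, roster1, tz = "UTC")
  expect_equal(a$block_id, "B01")
  expect_equal(a$role, "JR_FLC")
  # a shift starting at a block's first midnight belongs to that block
  first <- assign_blocks(utc_shift("T1", "2015-07-28 00:00:00", 600),
                         cal, roster1, tz = "UTC")
  expect_equal(first$block_id, "B02")
  # interval search agrees with a linear scan over the calendar
  set.seed(9)
  days <- sample(0:365, 40, replace = TRUE)
  shifts <- utc_shift("T1", format(as.Date("2015-06-29") + days, "%Y-%m-%d 12:00:00"), 60)
  got <- assign_blocks(shifts, cal, roster1, tz = "UTC")$block_id
  scan <- vapply(as.Date("2015-06-29") + days, function(d) {
    hit <- NA_character_
    for (i in seq_len(nrow(cal))) {
      if (d >= cal$start_date[i] && d < cal$end_date[i]) hit <- cal$block_id[i]
    }
    hit
  }, character(1))
  expect_equal(got, scan)
})

test_that("out-of-calendar shifts error; unrostered trainee-blocks are excluded", {
  expect_error(assign_blocks(utc_shift("T1", "2017-01-01 08:00:00", 60),
                             cal, roster1, tz = "UTC"),
               "outside block calendar")
  expect_error(assign_blocks(utc_shift("T1", "2015-06-01 08:00:00", 60),
                             cal, roster1, tz = "UTC"),
               "outside block calendar")
  stray <- utc_shift(c("T1", "T9"), c("2015-07-01 08:00:00", "2015-07-01 08:00:00"), 600)
  expect_warning(a <- assign_blocks(stray, cal, roster1, tz = "UTC"),
                 "without roster assignment")
  expect_equal(a$trainee_id, "T1")
  expect_equal(nrow(attr(a, "excluded_shifts")), 1L)
})

test_that("resident-block tallies match a hand-tallied fixture and conserve counts", {
  roster <- tibble::tibble(
    trainee_id = c("A", "A", "B", "C"), pgy = c(1L, 1L, 2L, 2L),
    block_id = c("B01", "B02", "B01", "B01"),
    role = c("JR_FLC", "JR_FLC", "SR_FLC", "SR_SUPRV"),
    rotation = "WARDS"
  )
  # A/B01: two EDS duration violations + one interval; B/B01: one EDS + one
  # SRS with no violations; C and A/B02: no shifts at all
  eds <- dplyr::bind_rows(
    utc_shift("A", "2015-07-01 00:00:00", 1000),            # JR duration (+40)
    utc_shift("A", "2015-07-02 00:40:00", 970),             # duration + interval
    utc_shift("B", "2015-07-01 08:00:00", 600)
  )
  srs <- utc_shift("B", "2015-07-01 08:00:00", 600, source = "SELF_REPORTED")
  shifts <- assign_blocks(dplyr::bind_rows(eds, srs), cal, roster, tz = "UTC")
  viol <- detect_violations(shifts, duty_hour_rules())
  tal <- tally_blocks(shifts, viol, roster)
  expect_equal(nrow(tal), 4L)  # one row per roster assignment
  a1 <- tal[tal$trainee_id == "A" & tal$block_id == "B01", ]
  expect_equal(a1$edv_duration, 2L)
  expect_equal(a1$edv_interval, 1L)
  expect_equal(a1$edv_total, 3L)
  expect_equal(a1$n_srs, 0L)
  b1 <- tal[tal$trainee_id == "B" & tal$block_id == "B01", ]
  expect_equal(c(b1$n_eds, b1$n_srs, b1$edv_total, b1$srv_total), c(1L, 1L, 0L, 0L))
  expect_equal(tal[tal$trainee_id == "C", ]$n_eds, 0L)
  # conservation: tallies sum to the violation list, per source and type
  expect_equal(sum(tal$edv_duration),
               sum(viol$source == "EHR_DEFINED" & viol$type == "DURATION"))
  expect_equal(sum(tal$edv_interval),
               sum(viol$source == "EHR_DEFINED" & viol$type == "INTERVAL"))
  expect_equal(sum(tal$srv_total), sum(viol$source == "SELF_REPORTED"))
  # a violation referencing an absent shift is an error
  ghost <- viol
  ghost$shift_start[1] <- ghost$shift_start[1] + 1
  expect_error(tally_blocks(shifts, ghost, roster), "not present")
})

mk_tallies <- function(edv, srv, n_srs = 1L, role = "JR_FLC") {
  n <- length(edv)
  tibble::tibble(
    trainee_id = sprintf("T%03d", seq_len(n)), block_id = "B01", role = role,
    rotation = "WARDS", n_eds = 1L, n_srs = n_srs,
    edv_duration = as.integer(edv), edv_interval = 0L, edv_total = as.integer(edv),
    srv_duration = as.integer(srv), srv_interval = 0L, srv_total = as.integer(srv)
  )
}

test_that("zero-SRS blocks are excluded with consistent bookkeeping", {
  tal <- mk_tallies(edv = c(1, 2, 0, 3, 1), srv = c(1, 0, 0, 1, 1),
                    n_srs = c(2L, 0L, 3L, 0L, 1L))
  ex <- exclude_unlogged_blocks(tal)
  expect_equal(nrow(ex$eligible), 3L)
  expect_true(all(ex$eligible$n_srs > 0))
  expect_equal(ex$report$n_blocks_excluded, 2L)
  expect_equal(ex$report$pct_blocks_excluded, 40)
  expect_equal(ex$report$n_blocks_eligible + ex$report$n_blocks_excluded,
               ex$report$n_blocks_total)
  # identity when everything is logged
  all_logged <- exclude_unlogged_blocks(mk_tallies(1:3, 1:3))
  expect_equal(nrow(all_logged$eligible), 3L)
  expect_equal(all_logged$report$pct_blocks_excluded, 0)
})

test_that("paired differences classify blocks and report percentages to one decimal", {
  tal <- mk_tallies(edv = c(3, 1, 2), srv = c(1, 1, 4))
  pd <- paired_difference(tal)
  expect_equal(pd$comparisons$diff, c(-2, 0, 2))
  expect_equal(pd$comparisons$class, c("UNDER", "EQUAL", "OVER"))
  expect_lt(abs(pd$summary$pct_under + pd$summary$pct_over + pd$summary$pct_equal - 100),
            0.15)  # sums to 100 up to one-decimal rounding
  # the proportions of a 222/108/273 split of 603 blocks
  big <- mk_tallies(edv = c(rep(1, 222), rep(0, 108), rep(0, 273)),
                    srv = c(rep(0, 222), rep(1, 108), rep(0, 273)))
  ps <- paired_difference(big)$summary
  expect_equal(ps$pct_under, 36.8)
  expect_equal(ps$pct_over, 17.9)
  expect_equal(ps$pct_equal, 45.3)
  expect_equal(sum(paired_difference(big)$histogram$count), 603L)
})

test_that("role summaries match closed-form ANOVA and Tukey to 1e-8", {
  set.seed(21)
  tal <- mk_tallies(edv = rpois(60, 2), srv = rpois(60, 1),
                    role = rep(c("JR_FLC", "SR_FLC", "SR_SUPRV"), each = 20))
  rs <- role_summary(tal, "EHR_DEFINED")
  ora <- oracle_anova(tal$edv_total, tal$role)
  expect_equal(rs$anova$f, ora$f, tolerance = 1e-10)
  expect_equal(rs$anova$p, ora$p, tolerance = 1e-10)
  ora_tk <- oracle_tukey(tal$edv_total, tal$role)
  got_tk <- stats::setNames(rs$tukey$p_adj, rs$tukey$comparison)
  for (nm in names(got_tk)) {
    rev_nm <- paste(rev(strsplit(nm, "-")[[1]]), collapse = "-")
    expect_equal(unname(got_tk[nm]),
                 unname(ora_tk[ifelse(nm %in% names(ora_tk), nm, rev_nm)]),
                 tolerance = 1e-8)
  }
  # SEM uses the n-1 sample standard deviation
  jr <- tal$edv_total[tal$role == "JR_FLC"]
  expect_equal(rs$summary$sem[rs$summary$role == "JR_FLC"], sd(jr) / sqrt(20))
  # means are invariant to row order and trainee relabeling
  shuf <- tal[sample(nrow(tal)), ]
  shuf$trainee_id <- rev(shuf$trainee_id)
  expect_equal(role_summary(shuf, "EHR_DEFINED")$summary, rs$summary)
})

test_that("degenerate role structure yields descriptives only, with warning", {
  tal <- mk_tallies(edv = c(1, 2, 3), srv = c(0, 1, 1),
                    role = c("JR_FLC", "JR_FLC", "SR_FLC"))
  expect_warning(rs <- role_summary(tal, "EHR_DEFINED"), "inference skipped")
  expect_null(rs$anova)
  expect_equal(nrow(rs$summary), 2L)
})

test_that("two-group ANOVA F equals the squared equal-variance t statistic", {
  set.seed(8)
  tal <- mk_tallies(edv = rpois(30, 2), srv = 0,
                    role = rep(c("JR_FLC", "SR_FLC"), each = 15))
  rs <- role_summary(tal, "EHR_DEFINED")
  tt <- t.test(edv_total ~ role, data = tal, var.equal = TRUE)
  expect_equal(rs$anova$f, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("the violations model equals the normal-equation solution", {
  # hand-built 8-block fixture spanning all roles and both sources
  tal <- mk_tallies(edv = c(2, 3, 1, 0), srv = c(1, 2, 1, 0),
                    role = c("JR_FLC", "SR_FLC", "SR_SUPRV", "JR_FLC"))
  fit <- fit_violation_model(tal)
  long <- fit$long
  X <- cbind(1, long$source_SRV, long$role_SR_FLC, long$role_SR_SUPRV)
  ora <- oracle_ols(X, long$total)
  expect_equal(unname(fit$coefficients$estimate), unname(ora$beta), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients$std_error), unname(ora$se), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients$p_value), unname(ora$p), tolerance = 1e-10)
  # a single-role cohort leaves the design rank deficient
  expect_error(fit_violation_model(mk_tallies(1:4, 1:4, role = "JR_FLC")),
               "role_SR")
})

test_that("an injected reporting deficit is recovered by the source coefficient", {
  set.seed(14)
  for (rep in 1:3) {
    edv <- rpois(300, 1.5)
    deficit <- rbinom(300, pmin(edv, 1L), 0.45)
    tal <- mk_tallies(edv = edv, srv = pmax(edv - deficit, 0),
                      role = sample(c("JR_FLC", "SR_FLC", "SR_SUPRV"), 300, TRUE))
    fit <- fit_violation_model(tal)
    est <- fit$coefficients$estimate[fit$coefficients$term == "source_SRV"]
    expect_lt(est, 0)
  }
})
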