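#' Duty-hour rules in force during the study era
#'
#' Maximum continuous shift duration is role-specific: 16 h (960 min) for
#' junior front-line clinicians (interns), 28 h (24+4 h, 1680 min) for
#' senior front-line and supervisory trainees; the 24+4 allowance is treated
#' as a single hard cap. Required rest between shifts is 8 h (480 min) after
#' shifts of at most 16 h, and 14 h (840 min) after shifts longer than 16 h.
#'
#' Boundary conventions (declared, and exercised by the test suite): a shift
#' of exactly the maximum is *not* a duration violation (strict `>`); the
#' short-shift class is inclusive (`<= 16 h`); rest exactly equal to the
#' requirement is adequate (violation requires strict `<`).
#'
#' @param max_jr,max_sr Role caps in minutes.
#' @param rest_short,rest_long Required rest in minutes after short/long shifts.
#' @param short_shift_cutoff Boundary between the two rest classes, minutes.
#' @return An object of class `duty_hour_rules`.
#' @export
duty_hour_rules <- function(max_jr = 960, max_sr = 1680,
                            rest_short = 480, rest_long = 840,
                            short_shift_cutoff = 960) {
  stopifnot(max_jr > 0, max_sr > 0, rest_short > 0, short_shift_cutoff > 0)
  if (rest_long <= rest_short) {
    stop("rest_long must exceed rest_short", call. = FALSE)
  }
  structure(list(
    max_duration_by_role = c(JR_FLC = max_jr, SR_FLC = max_sr, SR_SUPRV = max_sr),
    rest_short = rest_short, rest_long = rest_long,
    short_shift_cutoff = short_shift_cutoff
  ), class = "duty_hour_rules")
}

#' Required rest after a shift of a given duration
#'
#' @param prior_shift_duration Duration(s) of the preceding shift, minutes.
#' @param rules A [duty_hour_rules()] object.
#' @return Required rest in minutes (vectorized).
#' @export
required_rest <- function(prior_shift_duration, rules = duty_hour_rules()) {
  stopifnot(all(prior_shift_duration > 0))
  ifelse(prior_shift_duration <= rules$short_shift_cutoff,
         rules$rest_short, rules$rest_long)
}

empty_violation_tbl <- function() {
  tibble::tibble(
    trainee_id = character(), source = character(), type = character(),
    shift_start = parse_instant(character()), shift_end = parse_instant(character()),
    magnitude_minutes = numeric()
  )
}

#' Detect duration violations for shifts worked in one role
#'
#' A duration violation is a shift strictly exceeding the role's maximum;
#' the magnitude is the excess in minutes.
#'
#' @param shifts Shift tibble for one trainee-role context.
#' @param role One of `"JR_FLC"`, `"SR_FLC"`, `"SR_SUPRV"`.
#' @param rules A [duty_hour_rules()] object.
#' @return Violation tibble (`type = "DURATION"`).
#' @export
detect_duration_violations <- function(shifts, role, rules = duty_hour_rules()) {
  if (!is.character(role) || length(role) != 1L || !role %in% names(rules$max_duration_by_role)) {
    stop(sprintf("unknown role: %s", paste(role, collapse = ", ")), call. = FALSE)
  }
  shifts$role <- role
  duration_violations_by_role(shifts, rules)
}

# Vectorized core: `shifts` carries a per-row `role` column (role can change
# across blocks within one trainee's year).
duration_violations_by_role <- function(shifts, rules) {
  bad_role <- setdiff(unique(shifts$role), names(rules$max_duration_by_role))
  if (length(bad_role) > 0L) {
    stop(sprintf("unknown role: %s", paste(bad_role, collapse = ", ")), call. = FALSE)
  }
  cap <- unname(rules$max_duration_by_role[shifts$role])
  hit <- shifts$duration_minutes > cap
  out <- shifts[hit, , drop = FALSE]
  viol <- tibble::tibble(
    trainee_id = out$trainee_id, source = out$source, type = "DURATION",
    shift_start = out$start, shift_end = out$end,
    magnitude_minutes = out$duration_minutes - cap[hit]
  )
  carry_shift_context(viol, out)
}

# Keep block/role/rotation annotation from the offending shift if present.
carry_shift_context <- function(viol, shifts) {
  for (col in intersect(c("role", "block_id", "rotation"), names(shifts))) {
    viol[[col]] <- shifts[[col]]
  }
  viol
}

#' Detect interval (inadequate-rest) violations
#'
#' Examines each pair of consecutive shifts of one trainee and one source;
#' if the off-duty gap is strictly below the rest required after the earlier
#' shift, an INTERVAL violation is emitted, attributed to the *later* shift,
#' with magnitude equal to the rest shortfall. Pairs spanning block
#' boundaries are still checked.
#'
#' @param shifts Sorted, non-overlapping shift tibble (grouped internally by
#'   trainee and source).
#' @param rules A [duty_hour_rules()] object.
#' @return Violation tibble (`type = "INTERVAL"`).
#' @export
detect_interval_violations <- function(shifts, rules = duty_hour_rules()) {
  if (nrow(shifts) < 2L) return(empty_violation_tbl())
  check_shift_tbl(shifts, "interval check")
  shifts |>
    dplyr::group_by(.data$trainee_id, .data$source) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      if (n < 2L) {
        return(tibble::tibble(type = character(), shift_start = d$start[0],
                              shift_end = d$end[0], magnitude_minutes = numeric()))
      }
      gap <- mins_between(d$end[-n], d$start[-1L])
      req <- required_rest(d$duration_minutes[-n], rules)
      hit <- which(gap < req)
      later <- d[hit + 1L, , drop = FALSE]
      viol <- tibble::tibble(
        type = rep("INTERVAL", length(hit)),
        shift_start = later$start, shift_end = later$end,
        magnitude_minutes = req[hit] - gap[hit]
      )
      carry_shift_context(viol, later)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("trainee_id", "source", "type")
}

#' Detect all duty-hour violations over a role-annotated shift table
#'
#' The engine is agnostic to shift source: applied to EHR-defined shifts it
#' yields EDV inputs, to self-reported shifts SRV inputs. `shifts` must
#' carry a per-row `role` column (from [assign_blocks()] or the simulator).
#'
#' @param shifts Role-annotated shift tibble (any mix of trainees/sources).
#' @param rules A [duty_hour_rules()] object.
#' @return Violation tibble with both DURATION and INTERVAL rows, sorted by
#'   trainee, source, shift start.
#' @export
detect_violations <- function(shifts, rules = duty_hour_rules()) {
  if (nrow(shifts) == 0L) return(empty_violation_tbl())
  if (!"role" %in% names(shifts)) {
    stop("detect_violations requires a `role` column (run assign_blocks first)",
         call. = FALSE)
  }
  check_shift_tbl(shifts, "violation detection")
  out <- dplyr::bind_rows(
    duration_violations_by_role(shifts, rules),
    detect_interval_violations(shifts, rules)
  )
  dplyr::arrange(out, .data$trainee_id, .data$source, .data$shift_start, .data$type)
}

#' Summarize excess duration across duration violations
#'
#' Median and quartiles (linear-interpolation, type-7 quantiles) of the
#' violation magnitudes, in minutes.
#'
#' @param duration_violations Violation tibble (rows of other types are
#'   ignored).
#' @return A one-row tibble `n, median, q1, q3`; `n = 0` with `NA` quantiles
#'   for empty input.
#' @export
excess_duration_stats <- function(duration_violations) {
  m <- duration_violations$magnitude_minutes[duration_violations$type == "DURATION"]
  if (length(m) == 0L) {
    return(tibble::tibble(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(m, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(m), median = q[2L], q1 = q[1L], q3 = q[3L])
}
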