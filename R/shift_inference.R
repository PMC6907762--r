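#' Segmentation parameters for shift inference
#'
#' The sessionization heuristic has three knobs, all in minutes:
#' `long_gap_threshold` is the inter-event gap at or beyond which a new
#' shift begins (within-shift gaps are strictly smaller); during refinement,
#' candidate shifts separated by less than `merge_gap` are merged, and
#' shifts shorter than `min_shift_duration` are then discarded.
#' `start_pad`/`end_pad` extend every final shift outward to account for
#' work before the first and after the last EHR event (default 0: endpoints
#' are the observed events, which under-estimates but never over-estimates
#' time on duty).
#'
#' @param long_gap_threshold Boundary-defining gap, minutes (default 300).
#' @param merge_gap Refinement merge threshold, minutes (default 60).
#' @param min_shift_duration Minimum retained shift length, minutes (default 60).
#' @param start_pad,end_pad Outward padding, minutes (default 0).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(long_gap_threshold = 300, merge_gap = 60,
                                min_shift_duration = 60,
                                start_pad = 0, end_pad = 0) {
  stopifnot(long_gap_threshold > 0, merge_gap >= 0, min_shift_duration >= 0,
            start_pad >= 0, end_pad >= 0)
  if (merge_gap >= long_gap_threshold) {
    stop("merge_gap must be smaller than long_gap_threshold", call. = FALSE)
  }
  structure(list(long_gap_threshold = long_gap_threshold, merge_gap = merge_gap,
                 min_shift_duration = min_shift_duration,
                 start_pad = start_pad, end_pad = end_pad),
            class = "segmentation_params")
}

#' Inter-event intervals for one trainee
#'
#' @param events Access-log tibble for a single trainee, sorted ascending.
#' @return A tibble with `preceding_event` (index of the earlier event) and
#'   `gap_minutes`; empty for fewer than two events.
#' @export
compute_intervals <- function(events) {
  if (length(unique(events$trainee_id)) > 1L) {
    stop("compute_intervals expects events of a single trainee", call. = FALSE)
  }
  n <- nrow(events)
  if (n < 2L) {
    return(tibble::tibble(preceding_event = integer(), gap_minutes = numeric()))
  }
  if (is.unsorted(events$timestamp)) {
    stop("events must be sorted ascending by timestamp", call. = FALSE)
  }
  tibble::tibble(
    preceding_event = seq_len(n - 1L),
    gap_minutes = mins_between(events$timestamp[-n], events$timestamp[-1L])
  )
}

#' Sessionize one trainee's event stream into candidate shifts
#'
#' Candidate shifts are maximal runs of consecutive events whose internal
#' gaps are all strictly below `long_gap_threshold`; a gap exactly equal to
#' the threshold starts a new shift. Shift start/end are the first/last
#' event timestamps of the run.
#'
#' @param events Sorted, on-site-filtered events of one trainee.
#' @param params A [segmentation_params()] object.
#' @return Shift tibble with `source = "EHR_DEFINED"`, in time order.
#' @export
segment_shifts <- function(events, params = segmentation_params()) {
  if (nrow(events) == 0L) {
    return(new_shift_tbl(character(), parse_instant(character()),
                         parse_instant(character()), "EHR_DEFINED"))
  }
  iv <- compute_intervals(events)
  boundary <- c(TRUE, iv$gap_minutes >= params$long_gap_threshold)
  run <- cumsum(boundary)
  start <- events$timestamp[!duplicated(run)]
  end <- events$timestamp[!duplicated(run, fromLast = TRUE)]
  tibble::tibble(
    trainee_id = events$trainee_id[1L],
    start = start, end = end,
    source = "EHR_DEFINED",
    duration_minutes = mins_between(start, end)
  )
}

#' Refine candidate shifts: merge, then filter
#'
#' Consecutive candidates separated by less than `merge_gap` are merged
#' (chains collapse into one shift), and shifts with duration below
#' `min_shift_duration` are then discarded. Merging is applied before
#' discarding, so two short fragments close together can survive as one
#' merged shift.
#'
#' @param shifts Sorted, non-overlapping candidate shifts of one trainee.
#' @param params A [segmentation_params()] object.
#' @return Refined shift tibble.
#' @export
refine_shifts <- function(shifts, params = segmentation_params()) {
  if (nrow(shifts) == 0L) return(shifts)
  n <- nrow(shifts)
  gap <- mins_between(shifts$end[-n], shifts$start[-1L])
  if (any(gap < 0)) stop("refine_shifts: candidates overlap", call. = FALSE)
  grp <- cumsum(c(TRUE, gap >= params$merge_gap))
  start <- shifts$start[!duplicated(grp)]
  end <- shifts$end[!duplicated(grp, fromLast = TRUE)]
  out <- tibble::tibble(
    trainee_id = shifts$trainee_id[1L],
    start = start, end = end,
    source = shifts$source[1L],
    duration_minutes = mins_between(start, end)
  )
  out[out$duration_minutes >= params$min_shift_duration, , drop = FALSE]
}

#' Infer EHR-defined shifts for every trainee in an event stream
#'
#' Applies interval computation, sessionization and refinement per trainee,
#' then the configured start/end padding. Deterministic for fixed input and
#' parameters; trainees are processed independently.
#'
#' @param events Validated, on-site-filtered access-log tibble (any number
#'   of trainees).
#' @param params A [segmentation_params()] object.
#' @return Shift tibble (`source = "EHR_DEFINED"`) across all trainees,
#'   sorted by trainee then start.
#' @export
infer_all_shifts <- function(events, params = segmentation_params()) {
  pieces <- lapply(split(events, events$trainee_id), function(ev) {
    ev <- ev[order(ev$timestamp), , drop = FALSE]
    refine_shifts(segment_shifts(ev, params), params)
  })
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0L) {
    return(new_shift_tbl(character(), parse_instant(character()),
                         parse_instant(character()), "EHR_DEFINED"))
  }
  if (params$start_pad > 0 || params$end_pad > 0) {
    out$start <- out$start - params$start_pad * 60
    out$end <- out$end + params$end_pad * 60
    out$duration_minutes <- mins_between(out$start, out$end)
  }
  out <- dplyr::arrange(out, .data$trainee_id, .data$start)
  check_shift_tbl(out, "inferred shifts")
}
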