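# Internal helpers shared across modules.

ROLES <- c("JR_FLC", "SR_FLC", "SR_SUPRV")
SHIFT_SOURCES <- c("EHR_DEFINED", "SELF_REPORTED")
VIOLATION_TYPES <- c("DURATION", "INTERVAL")

#' @importFrom rlang %||% .data
NULL

# Minutes from a to b as a plain numeric (difftime units are not trusted
# implicitly anywhere in the package).
mins_between <- function(a, b) {
  as.numeric(difftime(b, a, units = "mins"))
}

fmt_utc <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

# Parse ISO 8601 timestamps (with or without a zone offset) to POSIXct in
# UTC. Returns NA where parsing fails; callers decide how to report.
parse_instant <- function(x) {
  suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
}

stop_rows <- function(file, lines, what) {
  shown <- utils::head(lines, 10L)
  more <- if (length(lines) > 10L) sprintf(" (and %d more)", length(lines) - 10L) else ""
  stop(sprintf("%s: %s at line(s) %s%s", file, what,
               paste(shown, collapse = ", "), more), call. = FALSE)
}

assert_cols <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

# Construct a validated shift table. `start`/`end` are POSIXct (UTC);
# duration is derived, never supplied.
new_shift_tbl <- function(trainee_id, start, end, source) {
  stopifnot(source %in% SHIFT_SOURCES)
  out <- tibble::tibble(
    trainee_id = as.character(trainee_id),
    start = start,
    end = end,
    source = source,
    duration_minutes = mins_between(start, end)
  )
  dplyr::arrange(out, .data$trainee_id, .data$start)
}

# Shift-table invariants: end > start; per trainee x source sorted and
# pairwise non-overlapping.
check_shift_tbl <- function(shifts, context = "shifts") {
  if (nrow(shifts) == 0L) return(invisible(shifts))
  if (any(shifts$duration_minutes <= 0)) {
    stop(sprintf("%s: found shift with end <= start", context), call. = FALSE)
  }
  bad <- shifts |>
    dplyr::group_by(.data$trainee_id, .data$source) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = any(dplyr::lead(.data$start) < .data$end, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$overlap)
  if (nrow(bad) > 0L) {
    stop(sprintf("%s: overlapping shifts for trainee(s) %s", context,
                 paste(unique(bad$trainee_id), collapse = ", ")), call. = FALSE)
  }
  invisible(shifts)
}
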