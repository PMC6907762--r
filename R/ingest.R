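#' Read an EHR access-log export
#'
#' Reads per-event audit rows (`trainee_id,timestamp,workstation_id,event_code`),
#' parses timestamps as ISO 8601 and normalizes them to UTC, collapses rows
#' that are exact duplicates across all four columns, and sorts ascending by
#' trainee then timestamp. Near-duplicates (same second, different event
#' code) are retained: the downstream shift-inference algorithm uses only
#' timestamps, and audit exports commonly repeat rows.
#'
#' @param path Path to the access-log CSV.
#' @return A tibble with columns `trainee_id`, `timestamp` (POSIXct, UTC),
#'   `workstation_id`, `event_code`. Row counts before and after
#'   de-duplication are reported via `message()`.
#' @export
read_access_log <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warning(sprintf("%s: empty access log", path), call. = FALSE)
    return(tibble::tibble(trainee_id = character(), timestamp = parse_instant(character()),
                          workstation_id = character(), event_code = character()))
  }
  assert_cols(raw, c("trainee_id", "timestamp", "workstation_id", "event_code"), path)
  ts <- parse_instant(raw$timestamp)
  bad <- which(is.na(ts))
  if (length(bad) > 0L) {
    stop_rows(path, bad + 1L, "unparseable timestamp")  # +1 for header line
  }
  n_raw <- nrow(raw)
  out <- tibble::tibble(
    trainee_id = raw$trainee_id,
    timestamp = ts,
    workstation_id = raw$workstation_id,
    event_code = raw$event_code
  ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$trainee_id, .data$timestamp)
  message(sprintf("access log: %d rows read, %d after de-duplication", n_raw, nrow(out)))
  out
}

#' Read a workstation directory
#'
#' @param path CSV with columns `workstation_id,onsite` where `onsite` is 0/1.
#' @return A tibble with `workstation_id` (character) and `onsite` (logical).
#' @export
read_workstations <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_cols(raw, c("workstation_id", "onsite"), path)
  onsite <- raw$onsite %in% c("1", "TRUE", "true")
  bad <- which(!raw$onsite %in% c("0", "1", "TRUE", "FALSE", "true", "false"))
  if (length(bad) > 0L) stop_rows(path, bad + 1L, "onsite flag must be 0/1")
  tibble::tibble(workstation_id = raw$workstation_id, onsite = onsite)
}

#' Drop events recorded at known off-site workstations
#'
#' Events whose workstation is listed with `onsite = FALSE` are removed.
#' Workstations absent from the directory are retained: exclusion is
#' evidence-based (only stations known to sit outside the hospital are
#' dropped), and the number of events at unlisted stations is reported.
#'
#' @param events Validated access-log tibble from [read_access_log()].
#' @param directory Workstation directory from [read_workstations()].
#' @return The filtered event tibble, with attribute `n_unknown_workstation`
#'   giving the number of retained events at unlisted stations.
#' @export
filter_onsite <- function(events, directory) {
  idx <- match(events$workstation_id, directory$workstation_id)
  onsite <- directory$onsite[idx]
  unknown <- is.na(idx)
  n_unknown <- sum(unknown)
  if (n_unknown > 0L) {
    message(sprintf("filter_onsite: %d event(s) at unlisted workstation(s) retained", n_unknown))
  }
  out <- events[unknown | onsite, , drop = FALSE]
  attr(out, "n_unknown_workstation") <- n_unknown
  out
}

#' Read a trainee roster
#'
#' One row per trainee-block assignment. Validates that PGY is an integer in
#' 1..4, that roles are one of `JR_FLC`, `SR_FLC`, `SR_SUPRV`, that junior
#' front-line clinicians are PGY-1 and senior roles PGY >= 2, and that each
#' trainee has at most one assignment per block.
#'
#' @param path CSV with columns `trainee_id,pgy,block_id,role,rotation`.
#' @return A tibble with those five columns (`pgy` integer).
#' @export
read_roster <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_cols(raw, c("trainee_id", "pgy", "block_id", "role", "rotation"), path)
  pgy <- suppressWarnings(as.integer(raw$pgy))
  bad_pgy <- which(is.na(pgy) | pgy < 1L | pgy > 4L)
  if (length(bad_pgy) > 0L) stop_rows(path, bad_pgy + 1L, "pgy must be an integer in 1..4")
  bad_role <- which(!raw$role %in% ROLES)
  if (length(bad_role) > 0L) stop_rows(path, bad_role + 1L, "unknown role")
  bad_jr <- which(raw$role == "JR_FLC" & pgy != 1L)
  if (length(bad_jr) > 0L) stop_rows(path, bad_jr + 1L, "JR_FLC requires pgy = 1")
  bad_sr <- which(raw$role != "JR_FLC" & pgy < 2L)
  if (length(bad_sr) > 0L) stop_rows(path, bad_sr + 1L, "senior roles require pgy >= 2")
  dup <- duplicated(raw[c("trainee_id", "block_id")])
  if (any(dup)) stop_rows(path, which(dup) + 1L, "duplicate trainee-block assignment")
  tibble::tibble(
    trainee_id = raw$trainee_id, pgy = pgy, block_id = raw$block_id,
    role = raw$role, rotation = raw$rotation
  )
}

#' Read a block calendar
#'
#' Blocks must be listed in order, contiguous and non-overlapping: each
#' block's start date must equal the previous start plus the previous
#' length.
#'
#' @param path CSV with columns `block_id,start_date,length_days`.
#' @return A tibble with `block_id`, `start_date` (Date), `length_days`
#'   (integer) and a derived exclusive `end_date` (= next block's start).
#' @export
read_block_calendar <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_cols(raw, c("block_id", "start_date", "length_days"), path)
  start <- suppressWarnings(as.Date(raw$start_date))
  bad <- which(is.na(start))
  if (length(bad) > 0L) stop_rows(path, bad + 1L, "unparseable start_date")
  len <- suppressWarnings(as.integer(raw$length_days))
  bad_len <- which(is.na(len) | len <= 0L)
  if (length(bad_len) > 0L) stop_rows(path, bad_len + 1L, "length_days must be a positive integer")
  if (nrow(raw) > 1L) {
    gap <- which(start[-1L] != start[-nrow(raw)] + len[-nrow(raw)])
    if (length(gap) > 0L) {
      stop_rows(path, gap + 2L, "blocks must be contiguous and non-overlapping")
    }
  }
  tibble::tibble(block_id = raw$block_id, start_date = start,
                 length_days = len, end_date = start + len)
}

#' Read a self-reported shift export
#'
#' Rows with `end <= start` are rejected row-wise and reported. Overlapping
#' shifts for one trainee are handled per `overlap_policy`: `"reject"`
#' (default) raises an error naming the trainee; `"merge"` unions the
#' overlapping intervals.
#'
#' @param path CSV with columns `trainee_id,start,end` (ISO 8601).
#' @param overlap_policy `"reject"` or `"merge"`.
#' @return A shift tibble with `source = "SELF_REPORTED"` and
#'   `duration_minutes`, sorted by trainee and start.
#' @export
read_self_reports <- function(path, overlap_policy = c("reject", "merge")) {
  overlap_policy <- match.arg(overlap_policy)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  assert_cols(raw, c("trainee_id", "start", "end"), path)
  start <- parse_instant(raw$start)
  end <- parse_instant(raw$end)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) stop_rows(path, bad + 1L, "unparseable timestamp")
  nonpos <- end <= start
  if (any(nonpos)) {
    message(sprintf("self reports: rejected %d row(s) with end <= start (line(s) %s)",
                    sum(nonpos), paste(utils::head(which(nonpos) + 1L, 10L), collapse = ", ")))
  }
  out <- new_shift_tbl(raw$trainee_id[!nonpos], start[!nonpos], end[!nonpos],
                       "SELF_REPORTED")
  overlapping <- out |>
    dplyr::group_by(.data$trainee_id) |>
    dplyr::summarise(any = any(dplyr::lead(.data$start) < .data$end, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$any)
  if (nrow(overlapping) > 0L) {
    if (overlap_policy == "reject") {
      stop(sprintf("%s: overlapping self-reported shifts for trainee(s) %s", path,
                   paste(overlapping$trainee_id, collapse = ", ")), call. = FALSE)
    }
    out <- merge_overlapping_shifts(out)
  }
  check_shift_tbl(out, "self reports")
}

# Union overlapping/abutting intervals within each trainee (one source).
merge_overlapping_shifts <- function(shifts) {
  shifts |>
    dplyr::group_by(.data$trainee_id, .data$source) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(grp = cumsum(c(TRUE, (.data$start > cummax(as.numeric(.data$end)))[-1L]))) |>
    dplyr::group_by(.data$trainee_id, .data$source, .data$grp) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    (\(d) new_shift_tbl(d$trainee_id, d$start, d$end, d$source[1L]))()
}

#' Write a shift table to CSV
#'
#' Timestamps are serialized as ISO 8601 UTC (`...Z`), so a written table
#' read back with [read_self_reports()] (or re-parsed with the same
#' conventions) round-trips exactly to the second.
#'
#' @param shifts A shift tibble.
#' @param path Output CSV path.
#' @export
write_shifts <- function(shifts, path) {
  out <- tibble::tibble(
    trainee_id = shifts$trainee_id,
    start = fmt_utc(shifts$start),
    end = fmt_utc(shifts$end),
    source = shifts$source,
    duration_minutes = shifts$duration_minutes
  )
  readr::write_csv(out, path)
  invisible(path)
}
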