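# Shared fixtures and independent oracles, built in code.

T0 <- as.POSIXct("2015-07-01 00:00:00", tz = "UTC")

ts_utc <- function(mins) T0 + mins * 60

mk_events <- function(trainee, mins, ws = "WS-H001", code = "LOGIN") {
  tibble::tibble(trainee_id = trainee, timestamp = ts_utc(mins),
                 workstation_id = ws, event_code = code)
}

mk_shifts <- function(trainee, start_min, end_min, source = "EHR_DEFINED") {
  tibble::tibble(trainee_id = trainee, start = ts_utc(start_min),
                 end = ts_utc(end_min), source = source,
                 duration_minutes = end_min - start_min)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Brute-force sessionization oracle: walk the sorted timestamps and start a
# new run wherever the gap to the previous event reaches the threshold.
# Deliberately loop-based and independent of the vectorized implementation.
oracle_segment <- function(mins, threshold) {
  if (length(mins) == 0L) return(data.frame(start = numeric(), end = numeric()))
  mins <- sort(mins)
  starts <- mins[1]
  ends <- numeric()
  for (i in seq_along(mins)[-1]) {
    if (mins[i] - mins[i - 1] >= threshold) {
      ends <- c(ends, mins[i - 1])
      starts <- c(starts, mins[i])
    }
  }
  data.frame(start = starts, end = c(ends, mins[length(mins)]))
}

# Random event stream in whole minutes (audit-log resolution): mixture of
# short (on-shift) and long (off-shift) gaps, plus occasional gaps exactly
# at the threshold so the tie-break rule is exercised.
random_stream <- function(n, threshold = 300) {
  gaps <- sample(c(sample.int(round(threshold * 1.5), n, replace = TRUE),
                   rep(threshold, ceiling(n / 10))), n - 1)
  cumsum(c(sample.int(60, 1), gaps))
}

# Closed-form one-way ANOVA (sums of squares computed directly).
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  m <- mean(values)
  sp <- split(values, groups)
  k <- length(sp)
  n <- length(values)
  ssb <- sum(vapply(sp, function(x) length(x) * (mean(x) - m)^2, numeric(1)))
  ssw <- sum(vapply(sp, function(x) sum((x - mean(x))^2), numeric(1)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE),
       mse = ssw / (n - k), df = n - k)
}

# Closed-form Tukey HSD adjusted p-values via the studentized range.
oracle_tukey <- function(values, groups) {
  groups <- as.character(groups)
  av <- oracle_anova(values, groups)
  sp <- split(values, groups)
  k <- length(sp)
  pairs <- utils::combn(names(sp), 2)
  out <- apply(pairs, 2, function(pr) {
    a <- sp[[pr[1]]]; b <- sp[[pr[2]]]
    se <- sqrt(av$mse / 2 * (1 / length(a) + 1 / length(b)))
    q <- abs(mean(a) - mean(b)) / se
    stats::ptukey(q, k, av$df, lower.tail = FALSE)
  })
  stats::setNames(out, apply(pairs, 2, paste, collapse = "-"))
}

# Closed-form OLS via the normal equations, with t-based p-values.
oracle_ols <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  resid <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  list(beta = beta, se = se,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

# Per-block EDV/SRV count comparison helper used by recovery tests.
block_counts <- function(violations) {
  violations |>
    dplyr::count(trainee_id, block_id, name = "n_viol") |>
    dplyr::arrange(trainee_id, block_id)
}
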