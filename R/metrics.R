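#' Buzz rate per hour of equivalent continuous recording
#'
#' Counts from a duty-cycled device cover only the recorded minutes of each
#' hour, so the rate is `count / recorded_minutes * 60`. Hours with zero
#' recorded minutes yield `NA` (missing), never zero: an unrecorded hour
#' carries no information.
#'
#' @param count Non-negative event count(s).
#' @param recorded_min Recorded minutes in the same interval.
#' @return Events per hour (numeric, `NA` where `recorded_min <= 0`).
#' @examples
#' buzz_per_hour(6, 12)   # 30
#' buzz_per_hour(13, 72)  # 10.8333...
#' @export
buzz_per_hour <- function(count, recorded_min) {
  stopifnot(all(count >= 0, na.rm = TRUE))
  ifelse(recorded_min > 0, count / recorded_min * 60, NA_real_)
}

#' Hourly activity series from detected events
#'
#' Bins absolute event times into device x hour rows over `[start, end)` and
#' attaches the schedule's recorded minutes for each hour, from which
#' [buzz_per_hour()] is computed. Devices with no events still get rows
#' (count 0) as long as they appear in `devices`.
#'
#' @param events Data.frame with columns `device_id`, `site_id`,
#'   `event_time` (`POSIXct`).
#' @param sched A [duty_cycle_schedule()].
#' @param start,end `POSIXct` bounds of the series (end exclusive); default
#'   the days spanned by the events.
#' @param devices Data.frame `device_id, site_id` enumerating devices;
#'   default the combinations present in `events`.
#' @return A data.frame `device_id, site_id, hour_start, buzz_count,
#'   recorded_min, buzz_per_hour`.
#' @export
activity_series <- function(events, sched, start = NULL, end = NULL,
                            devices = NULL) {
  if (is.null(start)) start <- as.POSIXct(trunc(min(events$event_time), "days"))
  if (is.null(end)) end <- as.POSIXct(trunc(max(events$event_time), "days")) + 86400
  if (is.null(devices))
    devices <- unique(events[c("device_id", "site_id")])
  hours <- seq(start, end - 1, by = "1 hour")
  rec_min <- vapply(seq_along(hours), function(i)
    recorded_minutes(sched, hours[i], hours[i] + 3600), 0)
  out <- do.call(rbind, lapply(seq_len(nrow(devices)), function(d) {
    ev <- events$event_time[events$device_id == devices$device_id[d]]
    cnt <- vapply(seq_along(hours), function(i)
      sum(ev >= hours[i] & ev < hours[i] + 3600), 0L)
    data.frame(device_id = devices$device_id[d], site_id = devices$site_id[d],
               hour_start = hours, buzz_count = cnt, recorded_min = rec_min)
  }))
  out$buzz_per_hour <- buzz_per_hour(out$buzz_count, out$recorded_min)
  rownames(out) <- NULL
  out
}

#' Absolute event times from batch-detection output
#'
#' @param det Result of [detect_batch()].
#' @return Data.frame `device_id, site_id, event_time` suitable for
#'   [activity_series()].
#' @export
detections_to_events <- function(det) {
  e <- det$events
  data.frame(device_id = e$device_id, site_id = e$site_id,
             event_time = parse_iso_time(e$start_time) + e$event_start_s)
}

#' Standardise traditional-survey counts by sampling effort
#'
#' Divides total (and flying-insect) abundance by the number of replicates,
#' putting hand-netting and pan-trap counts from sites with different
#' numbers of replicates on a common per-replicate scale.
#'
#' @param surveys Data.frame with columns `n_replicates`, `total_abundance`
#'   and optionally `flying_abundance`.
#' @return The input with added `std_total` (and `std_flying`) columns.
#' @export
standardize_counts <- function(surveys) {
  if (any(surveys$n_replicates < 1)) stop("n_replicates must be >= 1")
  stopifnot(all(surveys$total_abundance >= 0))
  surveys$std_total <- surveys$total_abundance / surveys$n_replicates
  if ("flying_abundance" %in% names(surveys)) {
    if (any(surveys$flying_abundance > surveys$total_abundance))
      stop("flying_abundance cannot exceed total_abundance")
    surveys$std_flying <- surveys$flying_abundance / surveys$n_replicates
  }
  surveys
}

#' Mean buzz/h at one hour of day across a site's devices
#'
#' Arithmetic mean of the hourly buzz rate over all devices (and days, if the
#' series spans several) of a site at a given hour of day, skipping missing
#' rows.
#'
#' @param activity An [activity_series()] table.
#' @param site Site id.
#' @param hour_of_day Integer 0-23.
#' @return Mean buzz/h (`NA` if no valid rows).
#' @export
hourly_site_mean <- function(activity, site, hour_of_day) {
  stopifnot(hour_of_day %in% 0:23)
  sel <- activity$site_id == site &
    as.numeric(format(activity$hour_start, "%H")) == hour_of_day
  v <- activity$buzz_per_hour[sel]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

#' Temperature-binned activity (mean +/- SE)
#'
#' Joins hourly activity rows to an hourly temperature series on
#' `(site_id, hour_start)` and bins them by temperature using left-closed,
#' right-open intervals at the given edges; the last bin is open above
#' ("30+" with the default edges) and readings below the first edge fall in
#' a "<low" bin. SE is the sample standard deviation (n - 1) over
#' `sqrt(n)`. Hours lacking a temperature reading are excluded with a
#' warning; hours with zero recorded minutes are skipped.
#'
#' @param activity An [activity_series()] table.
#' @param temps Data.frame `site_id, hour_start, temperature`.
#' @param edges Strictly increasing bin edges, deg C.
#' @return Data.frame `bin, t_low, t_high, n, mean_buzz_per_hour, se`.
#' @export
bin_by_temperature <- function(activity, temps, edges = c(15, 20, 25, 30)) {
  stopifnot(all(diff(edges) > 0))
  key_a <- paste(activity$site_id, as.numeric(activity$hour_start))
  key_t <- paste(temps$site_id, as.numeric(temps$hour_start))
  idx <- match(key_a, key_t)
  if (anyNA(idx[!is.na(activity$buzz_per_hour)]))
    warning("some hours lack temperature readings and were excluded")
  keep <- !is.na(idx) & !is.na(activity$buzz_per_hour)
  tt <- temps$temperature[idx[keep]]
  v <- activity$buzz_per_hour[keep]
  bin <- temperature_bin(tt, edges)
  labels <- temperature_bin_labels(edges)
  out <- do.call(rbind, lapply(seq_along(labels), function(b) {
    vb <- v[bin == b]
    data.frame(bin = labels[b],
               t_low = c(-Inf, edges)[b], t_high = c(edges, Inf)[b],
               n = length(vb),
               mean_buzz_per_hour = if (length(vb)) mean(vb) else NA_real_,
               se = if (length(vb) > 1) stats::sd(vb) / sqrt(length(vb)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

# left-closed bin index into 1..(length(edges)+1): 1 = below edges[1]
temperature_bin <- function(t, edges) findInterval(t, edges) + 1L

temperature_bin_labels <- function(edges) {
  k <- length(edges)
  c(paste0("<", edges[1]),
    if (k > 1) paste0(edges[-k], "-", edges[-1]),
    paste0(edges[k], "+"))
}

#' Pearson product-moment correlation with two-sided significance
#'
#' Sample correlation by the standard product-moment formula; the p-value
#' comes from the exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom. Perfectly collinear data return p = 0.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, neither constant.
#' @return A list with `r`, `p`, `n`.
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6))$r  # 1
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors with n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Weekly mean buzz/h: daytime window vs whole 24 h
#'
#' For each ISO week in the series, the mean hourly buzz rate across a
#' site's devices computed two ways: over daytime hours only (06:00-21:00 by
#' default) and over all 24 h. Used to ask whether restricting recording to
#' daylight changes the apparent activity level.
#'
#' @param activity An [activity_series()] table.
#' @param site Site id.
#' @param day_hours Integer hours of day counted as daytime.
#' @return Data.frame `week, mean_daytime, mean_24h` (weeks with no valid
#'   rows are dropped).
#' @export
compare_daytime_vs_24h <- function(activity, site, day_hours = 6:20) {
  a <- activity[activity$site_id == site & !is.na(activity$buzz_per_hour), ]
  if (nrow(a) == 0L) stop("no valid activity rows for site ", site)
  wk <- format(a$hour_start, "%G-W%V")
  hod <- as.numeric(format(a$hour_start, "%H"))
  weeks <- sort(unique(wk))
  out <- do.call(rbind, lapply(weeks, function(w) {
    sel <- wk == w
    data.frame(week = w,
               mean_daytime = mean(a$buzz_per_hour[sel & hod %in% day_hours]),
               mean_24h = mean(a$buzz_per_hour[sel]))
  }))
  out[!is.na(out$mean_24h), ]
}

#' Site x period mean buzz/h within a daily analysis window
#'
#' Averages the hourly buzz rate per site over a fixed daily time slot
#' (10:00-16:00 by default, matching the hours when traditional surveys are
#' run) and over the date range of each sampling period, yielding one value
#' per site x period for correlation against survey counts.
#'
#' @param activity An [activity_series()] table (any number of sites).
#' @param periods Data.frame `period, start, end` (`Date`s or strings; end
#'   inclusive).
#' @param window_hours Integer hours of day included (default 10:00-15:59).
#' @return Data.frame `site_id, period, buzz_per_hour`.
#' @export
site_period_buzz <- function(activity, periods, window_hours = 10:15) {
  hod <- as.numeric(format(activity$hour_start, "%H"))
  day <- as.Date(format(activity$hour_start, "%Y-%m-%d"))
  out <- list()
  for (i in seq_len(nrow(periods))) {
    sel <- hod %in% window_hours &
      day >= as.Date(periods$start[i]) & day <= as.Date(periods$end[i])
    a <- activity[sel & !is.na(activity$buzz_per_hour), ]
    if (nrow(a) == 0L) next
    m <- tapply(a$buzz_per_hour, a$site_id, mean)
    out[[i]] <- data.frame(site_id = names(m), period = periods$period[i],
                           buzz_per_hour = as.numeric(m))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate acoustic activity with standardised survey counts
#'
#' Joins site x period buzz rates to survey rows of one method and returns
#' the Pearson correlation between buzz/h and the per-replicate abundance.
#'
#' @param spb Output of [site_period_buzz()].
#' @param surveys A [standardize_counts()] table.
#' @param method Survey method to use (e.g. `"pan_trap"`, `"hand_netting"`).
#' @param measure `"total"` or `"flying"`.
#' @return A list with `r`, `p`, `n`, and the joined data in `$data`.
#' @export
correlate_surveys <- function(spb, surveys, method = "pan_trap",
                              measure = c("total", "flying")) {
  measure <- match.arg(measure)
  s <- surveys[surveys$method == method, ]
  col <- if (measure == "total") "std_total" else "std_flying"
  if (!col %in% names(s)) stop("surveys lack column ", col,
                               "; run standardize_counts() first")
  key_b <- paste(spb$site_id, spb$period)
  key_s <- paste(s$site_id, s$period)
  idx <- match(key_b, key_s)
  d <- data.frame(site_id = spb$site_id, period = spb$period,
                  buzz_per_hour = spb$buzz_per_hour,
                  std_count = s[[col]][idx])
  d <- d[!is.na(d$std_count), ]
  res <- pearson_r(d$buzz_per_hour, d$std_count)
  res$data <- d
  res
}
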