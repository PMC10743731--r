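#' Duty-cycled recording schedule
#'
#' Field devices trade energy for coverage by recording only part of each
#' cycle. A schedule is a set of daily periods, each with its own on/off
#' cycle; the default reproduces the regime used by the monitoring campaign:
#' 06:00-21:00 at 20\% duty cycle (12 min on, 48 min off) and 21:00-06:00 at
#' 4 min on / 56 min off, i.e. 216 recorded minutes per day. Cycles restart
#' (phase zero, "on" first) at each period boundary; on-windows are
#' half-open `[start, end)`. Periods must tile the 24 h day exactly; a
#' period may wrap midnight.
#'
#' @param periods A data.frame (or list coercible to one) with columns
#'   `start`, `end` ("HH:MM" daily times), `on_min`, `off_min` (minutes).
#' @return A `duty_cycle_schedule`.
#' @examples
#' sched <- duty_cycle_schedule()
#' recorded_minutes(sched, as.POSIXct("2023-05-01 00:00:00", tz = "UTC"),
#'                  as.POSIXct("2023-05-02 00:00:00", tz = "UTC"))  # 216
#' @export
duty_cycle_schedule <- function(periods = data.frame(
    start = c("06:00", "21:00"), end = c("21:00", "06:00"),
    on_min = c(12, 4), off_min = c(48, 56))) {
  periods <- as.data.frame(periods, stringsAsFactors = FALSE)
  stopifnot(all(c("start", "end", "on_min", "off_min") %in% names(periods)))
  p <- data.frame(
    start_min = hhmm_to_min(periods$start),
    end_min = hhmm_to_min(periods$end),
    on_min = as.numeric(periods$on_min),
    off_min = as.numeric(periods$off_min))
  if (any(p$on_min < 0) || any(p$off_min < 0) || any(p$on_min + p$off_min <= 0))
    stop("each period needs on_min >= 0, off_min >= 0, on + off > 0")
  p$len_min <- (p$end_min - p$start_min) %% 1440
  p$len_min[p$len_min == 0] <- 1440
  if (sum(p$len_min) != 1440)
    stop("periods must tile the 24 h day without overlap or gap")
  p <- p[order(p$start_min), ]
  if (nrow(p) > 1) {
    nxt <- c(p$start_min[-1], p$start_min[1] + 1440)
    if (any((p$start_min + p$len_min) != nxt))
      stop("periods must tile the 24 h day without overlap or gap")
  }
  structure(list(periods = p), class = "duty_cycle_schedule")
}

hhmm_to_min <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("times must be 'HH:MM': ", paste(x[bad], collapse = ", "))
  vapply(m, function(g) as.numeric(g[2]) * 60 + as.numeric(g[3]), 0)
}

#' Read a schedule from a JSON config
#'
#' The file holds a list of objects `{"start": "06:00", "end": "21:00",
#' "on_min": 12, "off_min": 48}`.
#'
#' @param path JSON path.
#' @return A [duty_cycle_schedule()].
#' @export
read_schedule <- function(path) {
  duty_cycle_schedule(jsonlite::read_json(path, simplifyVector = TRUE))
}

# All on-windows (as POSIXct start/end pairs) overlapping [start, end).
# Period instances are anchored at their daily start time; a wrapping night
# period is handled by also considering instances that began the day before.
on_windows_interval <- function(sched, start, end) {
  stopifnot(inherits(sched, "duty_cycle_schedule"), start < end)
  day0 <- as.POSIXct(trunc(start, "days")) - 86400   # previous day, for wrap
  days <- seq(day0, end, by = "1 day")
  out_s <- numeric(0); out_e <- numeric(0)
  s_num <- as.numeric(start); e_num <- as.numeric(end)
  for (d in as.numeric(days)) {
    for (i in seq_len(nrow(sched$periods))) {
      p <- sched$periods[i, ]
      p_start <- d + p$start_min * 60
      p_end <- p_start + p$len_min * 60
      if (p_end <= s_num || p_start >= e_num) next
      cyc <- (p$on_min + p$off_min) * 60
      k <- seq.int(0, ceiling(p$len_min * 60 / cyc) - 1)
      ws <- p_start + k * cyc
      we <- pmin(ws + p$on_min * 60, p_end)
      keep <- ws < p_end & we > s_num & ws < e_num & we > ws
      out_s <- c(out_s, ws[keep]); out_e <- c(out_e, we[keep])
    }
  }
  o <- order(out_s)
  data.frame(start = .POSIXct(out_s[o], tz = "UTC"),
             end = .POSIXct(out_e[o], tz = "UTC"))
}

#' On-windows of a schedule for one civil day
#'
#' Returns every on-window whose start falls within `day` (00:00 to 24:00).
#' Under the default schedule this is 24 windows: 15 daytime windows of
#' 12 min and 9 night windows of 4 min.
#'
#' @param sched A [duty_cycle_schedule()].
#' @param day A `Date` (or string coercible to one).
#' @return A data.frame with `POSIXct` columns `start` and `end`.
#' @export
on_windows <- function(sched, day) {
  day <- as.Date(day)
  d0 <- as.POSIXct(paste(day, "00:00:00"), tz = "UTC")
  w <- on_windows_interval(sched, d0, d0 + 86400)
  w[w$start >= d0 & w$start < d0 + 86400, , drop = FALSE]
}

#' Recorded minutes within an interval
#'
#' Total overlap, in minutes, between `[start, end)` and the schedule's
#' on-windows. Additive over disjoint intervals; a full default day yields
#' exactly 216 min, any daytime hour 12 min, any night hour 4 min.
#'
#' @param sched A [duty_cycle_schedule()].
#' @param start,end Interval bounds (`POSIXct`, or strings parseable by
#'   [as.POSIXct()]), `start < end`.
#' @return Minutes recorded (numeric).
#' @export
recorded_minutes <- function(sched, start, end) {
  if (is.character(start)) start <- as.POSIXct(start, tz = "UTC")
  if (is.character(end)) end <- as.POSIXct(end, tz = "UTC")
  w <- on_windows_interval(sched, start, end)
  if (nrow(w) == 0L) return(0)
  ov <- pmin(as.numeric(w$end), as.numeric(end)) -
    pmax(as.numeric(w$start), as.numeric(start))
  sum(pmax(0, ov)) / 60
}

#' Is a time instant recorded?
#'
#' Half-open convention: an instant exactly on an on-window boundary belongs
#' to the later state (so the end of an on-window is not recorded).
#'
#' @param sched A [duty_cycle_schedule()].
#' @param t `POSIXct` time(s).
#' @return Logical vector.
#' @export
is_recorded <- function(sched, t) {
  if (is.character(t)) t <- as.POSIXct(t, tz = "UTC")
  tn <- as.numeric(t)
  day_sec <- tn %% 86400
  res <- logical(length(tn))
  for (i in seq_len(nrow(sched$periods))) {
    p <- sched$periods[i, ]
    off <- (day_sec - p$start_min * 60) %% 86400
    inside <- off < p$len_min * 60
    cyc <- (p$on_min + p$off_min) * 60
    res <- res | (inside & (off %% cyc) < p$on_min * 60)
  }
  res
}
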