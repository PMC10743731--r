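# Independent oracle implementations used to cross-check the package.
# These deliberately avoid the code paths they verify.

# Exhaustive peak scan: every interior bin compared against both neighbours
# and the median-based floor, one bin at a time.
oracle_find_peaks <- function(freqs, power, threshold) {
  floor_db <- median(power)
  hits <- integer(0)
  for (i in seq_along(power)) {
    if (i == 1L || i == length(power)) next
    if (power[i] > power[i - 1L] && power[i] > power[i + 1L] &&
        power[i] > floor_db + threshold) hits <- c(hits, i)
  }
  data.frame(freq = freqs[hits], power = power[hits])
}

# Brute-force event grouping: scan candidate slots index by index, keeping an
# explicit member list; close on f0 break or on a gap longer than max_gap.
oracle_segment <- function(cands, cfg, window_seconds) {
  out <- list()
  members <- list()
  gap <- 0L
  flush <- function() {
    if (length(members) >= cfg$min_event_frames) {
      f0s <- sapply(members, function(m) m$f0)
      out[[length(out) + 1L]] <<- data.frame(
        start = members[[1L]]$time_offset,
        end = members[[length(members)]]$time_offset + window_seconds,
        f0_median = median(f0s), n_frames = length(members),
        peak_snr = max(sapply(members, function(m) m$snr)))
    }
    members <<- list()
  }
  for (k in seq_along(cands)) {
    c <- cands[[k]]
    if (is.null(c)) {
      if (length(members)) {
        gap <- gap + 1L
        if (gap > cfg$max_gap_frames) { flush(); gap <- 0L }
      }
      next
    }
    if (length(members)) {
      med <- median(sapply(members, function(m) m$f0))
      if (abs(c$f0 - med) > cfg$f0_track_tol) flush()
    }
    members[[length(members) + 1L]] <- c
    gap <- 0L
  }
  flush()
  if (!length(out))
    return(data.frame(start = numeric(0), end = numeric(0),
                      f0_median = numeric(0), n_frames = integer(0),
                      peak_snr = numeric(0)))
  do.call(rbind, out)
}

# Linear-scan temperature bin assignment (left-closed, right-open; open ends).
oracle_temp_bin <- function(t, edges) {
  b <- 1L
  for (e in edges) if (t >= e) b <- b + 1L
  b
}

# Random candidate pattern for segment_events equivalence testing.
random_candidates <- function(n_frames, hop = 0.1) {
  lapply(seq_len(n_frames), function(i) {
    if (runif(1) < 0.45) return(NULL)
    list(time_offset = (i - 1) * hop,
         f0 = sample(c(200, 210, 220, 400, 410), 1L) + runif(1, -3, 3),
         n_harmonics = sample(2:4, 1L), snr = runif(1, 10, 40))
  })
}
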