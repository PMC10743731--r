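#' Detector configuration
#'
#' Tunable parameters of the buzz detector. A frame is classified as
#' containing a buzz when a spectral peak inside `f0_range` is corroborated
#' by at least `min_harmonics` further peaks at integer multiples of its
#' frequency (within `harmonic_tol`); candidate frames are then merged into
#' events by f0-tracked run grouping.
#'
#' The defaults are engineering choices, exposed so they can be tuned:
#' wingbeat fundamentals of the target groups (Hymenoptera, Diptera,
#' Orthoptera) fall in 50-1000 Hz; `harmonic_tol` of 7.5 Hz is 1.5 analysis
#' bins; two confirmed harmonics and a 10 dB peak excess keep the
#' false-positive rate on stationary noise below one event per ten minutes
#' while retaining >= 95\% recall on clean synthetic buzzes.
#'
#' @param f0_range Fundamental-frequency search range, Hz (within the
#'   analysis band).
#' @param min_harmonics Minimum number of verified higher harmonics.
#' @param harmonic_tol Frequency tolerance for matching a peak to `k * f0`, Hz.
#' @param peak_threshold Peak height above the frame noise floor, dB.
#' @param min_event_frames Minimum run length (frames) for a valid event.
#' @param max_gap_frames Maximum bridged gap of non-candidate frames.
#' @param f0_track_tol Maximum deviation of a frame's f0 from the running
#'   event median, Hz.
#' @return A `detector_config` list.
#' @export
detector_config <- function(f0_range = c(50, 1000), min_harmonics = 2,
                            harmonic_tol = 7.5, peak_threshold = 10,
                            min_event_frames = 2, max_gap_frames = 1,
                            f0_track_tol = 15) {
  stopifnot(length(f0_range) == 2L, f0_range[1] > 4, f0_range[2] < 3000,
            f0_range[1] < f0_range[2], min_harmonics >= 1,
            harmonic_tol > 0, peak_threshold > 0, min_event_frames >= 1,
            max_gap_frames >= 0, f0_track_tol > 0)
  structure(list(f0_range = f0_range, min_harmonics = min_harmonics,
                 harmonic_tol = harmonic_tol, peak_threshold = peak_threshold,
                 min_event_frames = min_event_frames,
                 max_gap_frames = max_gap_frames, f0_track_tol = f0_track_tol),
            class = "detector_config")
}

#' Read a detector configuration from a JSON file
#'
#' The file holds an object whose names mirror the [detector_config()]
#' arguments; missing fields fall back to the defaults.
#'
#' @param path JSON config path.
#' @return A `detector_config`.
#' @export
read_detector_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(detector_config))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown detector config fields: ", paste(bad, collapse = ", "))
  do.call(detector_config, cfg)
}

#' Spectral peaks above the noise floor
#'
#' Local maxima (strictly greater than both neighbours; band-edge bins are
#' never peaks) whose power exceeds `noise_floor(frame) + threshold`,
#' sorted by frequency.
#'
#' @param frame A `spectral_frame`.
#' @param threshold Required excess over the noise floor, dB.
#' @return A data.frame with columns `freq` (Hz) and `power` (dB); zero rows
#'   when no peak qualifies.
#' @export
find_peaks <- function(frame, threshold = 10) {
  p <- frame$power
  n <- length(p)
  if (n < 3L) return(data.frame(freq = numeric(0), power = numeric(0)))
  i <- 2:(n - 1L)
  is_peak <- p[i] > p[i - 1L] & p[i] > p[i + 1L] &
    p[i] > noise_floor(frame) + threshold
  idx <- i[is_peak]
  data.frame(freq = frame$freqs[idx], power = p[idx])
}

#' Classify one frame as buzz candidate or not
#'
#' Among peaks whose frequency lies in `cfg$f0_range`, each is scored by the
#' number of peaks found within `cfg$harmonic_tol` of its integer multiples
#' `k * f0`, `k = 2, 3, ...`, up to the band edge. The candidate with the
#' most verified harmonics wins (ties broken by larger summed harmonic
#' power); harmonic-count scoring rather than raw peak height avoids locking
#' onto a dominant second harmonic. Returns `NULL` unless the winner has at
#' least `cfg$min_harmonics` verified harmonics.
#'
#' @param frame A `spectral_frame`.
#' @param cfg A [detector_config()].
#' @return `NULL`, or a list with `time_offset` (s), `f0` (Hz),
#'   `n_harmonics`, and `snr` (dB of the f0 peak over the noise floor).
#' @export
classify_frame <- function(frame, cfg = detector_config()) {
  pk <- find_peaks(frame, cfg$peak_threshold)
  if (nrow(pk) == 0L) return(NULL)
  cand <- pk[pk$freq >= cfg$f0_range[1] & pk$freq <= cfg$f0_range[2], , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  band_high <- max(frame$freqs)
  nf <- noise_floor(frame)
  best <- NULL
  for (j in seq_len(nrow(cand))) {
    f0 <- cand$freq[j]
    ks <- seq.int(2L, max(2L, floor(band_high / f0)))
    ks <- ks[ks * f0 <= band_high + cfg$harmonic_tol]
    nh <- 0L
    hpow <- 0
    for (k in ks) {
      d <- abs(pk$freq - k * f0)
      hit <- which(d <= cfg$harmonic_tol)
      if (length(hit)) {
        nh <- nh + 1L
        hpow <- hpow + max(pk$power[hit])
      }
    }
    if (is.null(best) || nh > best$nh || (nh == best$nh && hpow > best$hpow)) {
      best <- list(f0 = f0, nh = nh, hpow = hpow, snr = cand$power[j] - nf)
    }
  }
  if (best$nh < cfg$min_harmonics) return(NULL)
  list(time_offset = frame$time_offset, f0 = best$f0,
       n_harmonics = best$nh, snr = best$snr)
}

#' Merge candidate frames into buzz events
#'
#' Consecutive candidate frames whose fundamental stays within
#' `cfg$f0_track_tol` of the running median are merged into one event; runs
#' of up to `cfg$max_gap_frames` non-candidate frames are bridged; runs
#' shorter than `cfg$min_event_frames` are discarded. Event start/end come
#' from the first/last member frame, the end extended by one window length.
#'
#' @param cands A list, one element per frame in time order: the
#'   [classify_frame()] result or `NULL`.
#' @param cfg A [detector_config()].
#' @param window_seconds Analysis window length (s), used to extend the
#'   event end past the last frame onset.
#' @return A data.frame of events: `start`, `end` (s), `f0_median` (Hz),
#'   `n_frames`, `peak_snr` (dB).
#' @export
segment_events <- function(cands, cfg = detector_config(), window_seconds = 0.2) {
  events <- list()
  run <- NULL   # list(times, f0s, snrs)
  gap <- 0L
  close_run <- function(run) {
    if (!is.null(run) && length(run$times) >= cfg$min_event_frames) {
      events[[length(events) + 1L]] <<- data.frame(
        start = run$times[1L], end = run$times[length(run$times)] + window_seconds,
        f0_median = stats::median(run$f0s), n_frames = length(run$times),
        peak_snr = max(run$snrs))
    }
  }
  for (c in cands) {
    if (is.null(c)) {
      if (!is.null(run)) {
        gap <- gap + 1L
        if (gap > cfg$max_gap_frames) { close_run(run); run <- NULL; gap <- 0L }
      }
      next
    }
    if (!is.null(run) &&
        abs(c$f0 - stats::median(run$f0s)) <= cfg$f0_track_tol) {
      run$times <- c(run$times, c$time_offset)
      run$f0s <- c(run$f0s, c$f0)
      run$snrs <- c(run$snrs, c$snr)
    } else {
      close_run(run)
      run <- list(times = c$time_offset, f0s = c$f0, snrs = c$snr)
    }
    gap <- 0L
  }
  close_run(run)
  if (!length(events))
    return(data.frame(start = numeric(0), end = numeric(0),
                      f0_median = numeric(0), n_frames = integer(0),
                      peak_snr = numeric(0)))
  do.call(rbind, events)
}

#' Detect and count buzz events in a recording
#'
#' Runs the full per-recording chain: band-limited spectral frames at the
#' configured resolution, per-frame harmonic-pattern classification, and
#' f0-tracked event segmentation. Deterministic for fixed input and config,
#' and invariant under positive gain scaling of the waveform (all thresholds
#' are relative to the per-frame noise floor).
#'
#' @param rec An [audio_recording].
#' @param cfg A [detector_config()].
#' @param bin_width,band,hop_fraction Passed to [compute_frames()].
#' @return A list with `count` (integer) and `events` (data.frame as from
#'   [segment_events()]).
#' @examples
#' rec <- synth_scenario_recording(n_buzzes = 3, seed = 1)
#' count_buzzes(rec)$count
#' @export
count_buzzes <- function(rec, cfg = detector_config(), bin_width = 5,
                         band = c(4, 3000), hop_fraction = 0.5) {
  frames <- compute_frames(rec, bin_width = bin_width, band = band,
                           hop_fraction = hop_fraction)
  cands <- lapply(frames, classify_frame, cfg = cfg)
  ev <- segment_events(cands, cfg, window_seconds = frames[[1]]$window_seconds)
  list(count = nrow(ev), events = ev)
}

#' Batch detection over a manifest
#'
#' Applies [count_buzzes()] to every file in a recording manifest and
#' returns per-event and per-recording tables matching the CSV interfaces of
#' [write_detections()].
#'
#' @param manifest Data.frame from [read_manifest()], or a manifest CSV path.
#' @param cfg A [detector_config()].
#' @return A list of data.frames: `events` with columns `path, device_id,
#'   site_id, start_time, event_start_s, event_end_s, f0_hz, n_frames,
#'   peak_snr_db`; and `summary` with `path, device_id, site_id, start_time,
#'   duration_s, count`.
#' @export
detect_batch <- function(manifest, cfg = detector_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  ev_rows <- list()
  sm_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- read_wav(manifest$path[i], start_time = manifest$start_time[i],
                    device_id = manifest$device_id[i],
                    site_id = manifest$site_id[i])
    res <- count_buzzes(rec, cfg)
    sm_rows[[i]] <- data.frame(
      path = manifest$path[i], device_id = rec$device_id, site_id = rec$site_id,
      start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%S"),
      duration_s = duration_seconds(rec), count = res$count)
    if (res$count > 0) {
      ev_rows[[length(ev_rows) + 1L]] <- data.frame(
        path = manifest$path[i], device_id = rec$device_id,
        site_id = rec$site_id,
        start_time = format(rec$start_time, "%Y-%m-%dT%H:%M:%S"),
        event_start_s = res$events$start, event_end_s = res$events$end,
        f0_hz = res$events$f0_median, n_frames = res$events$n_frames,
        peak_snr_db = res$events$peak_snr)
    }
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(path = character(0), device_id = character(0),
               site_id = character(0), start_time = character(0),
               event_start_s = numeric(0), event_end_s = numeric(0),
               f0_hz = numeric(0), n_frames = integer(0),
               peak_snr_db = numeric(0))
  list(events = events, summary = do.call(rbind, sm_rows))
}

#' Write detection tables to CSV
#'
#' @param det Result of [detect_batch()].
#' @param events_path,summary_path Output CSV paths (`NULL` to skip either).
#' @return Invisibly, `det`.
#' @export
write_detections <- function(det, events_path = NULL, summary_path = NULL) {
  if (!is.null(events_path))
    utils::write.csv(det$events, events_path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(det$summary, summary_path, row.names = FALSE)
  invisible(det)
}
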