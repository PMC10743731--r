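#' Synthetic buzz specification
#'
#' A buzz is modelled as a harmonic stack: sinusoids at `f0, 2*f0, ...,
#' n_harmonics * f0`, each `harmonic_rolloff` dB quieter than the previous,
#' with independent random phases and a linear attack/release amplitude
#' envelope. This captures the defining spectral signature of insect
#' wingbeat sound — a fundamental at the wingbeat rate plus higher
#' harmonics — without attempting species-realistic timbre.
#'
#' @param f0 Fundamental frequency, Hz (wingbeat rate; 50-1000 Hz typical).
#' @param n_harmonics Number of partials including the fundamental.
#' @param harmonic_rolloff Level drop per successive harmonic, dB.
#' @param duration Buzz duration, seconds.
#' @param attack,release Envelope ramp times, seconds
#'   (`attack + release <= duration`).
#' @param amplitude Peak level, dBFS (0 = full scale).
#' @return A `buzz_spec` list.
#' @export
buzz_spec <- function(f0 = 220, n_harmonics = 4, harmonic_rolloff = 6,
                      duration = 0.5, attack = 0.05, release = 0.05,
                      amplitude = -20) {
  stopifnot(f0 > 0, n_harmonics >= 1, duration > 0, attack >= 0, release >= 0)
  if (attack + release > duration)
    stop("duration shorter than attack + release")
  structure(list(f0 = f0, n_harmonics = n_harmonics,
                 harmonic_rolloff = harmonic_rolloff, duration = duration,
                 attack = attack, release = release, amplitude = amplitude),
            class = "buzz_spec")
}

#' Render a synthetic buzz waveform
#'
#' Deterministic given `(spec, sample_rate, seed)`. Harmonics at or above
#' the Nyquist frequency are dropped silently. The waveform is scaled so its
#' peak equals `spec$amplitude` dBFS.
#'
#' @param spec A [buzz_spec()].
#' @param sample_rate Sampling rate, Hz.
#' @param seed Integer seed for the random harmonic phases.
#' @return Numeric amplitude vector of length `round(duration * sample_rate)`.
#' @export
synth_buzz <- function(spec, sample_rate = 8000, seed = 1L) {
  stopifnot(inherits(spec, "buzz_spec"))
  n <- as.integer(round(spec$duration * sample_rate))
  t <- (seq_len(n) - 1L) / sample_rate
  ks <- seq_len(spec$n_harmonics)
  ks <- ks[ks * spec$f0 < sample_rate / 2]
  phases <- local_rng(seed, function() stats::runif(length(ks), 0, 2 * pi))
  x <- numeric(n)
  for (i in seq_along(ks)) {
    a <- 10^(-spec$harmonic_rolloff * (ks[i] - 1) / 20)
    x <- x + a * sin(2 * pi * ks[i] * spec$f0 * t + phases[i])
  }
  env <- pmin(1,
              if (spec$attack > 0) t / spec$attack else 1,
              if (spec$release > 0) (spec$duration - t) / spec$release else 1)
  x <- x * pmax(0, env)
  peak <- max(abs(x))
  if (peak > 0) x <- x * 10^(spec$amplitude / 20) / peak
  x
}

# Run `fn` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards, so library randomness never perturbs user code.
local_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Stable per-device sub-seed so adding devices never perturbs existing
# streams. Kept below 2^31 - 1.
device_seed <- function(seed, device_index) {
  (as.numeric(seed) * 10007 + device_index * 97) %% 2147483629
}

#' Scenario specification for synthetic monitoring campaigns
#'
#' Defines a multi-day, multi-device scenario with a known ground truth:
#' buzz event times are drawn per device from an inhomogeneous Poisson
#' process whose hourly rate is
#' `base_rate * exp(-(T - T_opt)^2 / (2 * width^2)) * diurnal`,
#' where `T` is the hour's temperature, `diurnal` equals `diurnal_factor`
#' during daytime hours (06:00-21:00) and 1 at night, and the rate is forced
#' to zero during rain hours. The Gaussian thermal response with
#' `T_opt = 22.5` and `width = 5` places peak activity in the 20-25 deg C
#' band and suppresses it above 30 deg C, emulating the temperature
#' dependence reported for social-bee flight activity.
#'
#' @param days Number of days.
#' @param start_date First day (`Date` or string).
#' @param site_id Site tag.
#' @param n_devices Number of devices at the site.
#' @param base_rate Peak true buzz rate, events/h, at `T = T_opt` (night).
#' @param t_opt,width Thermal response optimum and Gaussian width, deg C.
#' @param rain_hours `POSIXct` vector of hour starts with rate forced to 0.
#' @param diurnal_factor Day/night rate ratio (>= 0).
#' @param noise_level Background white-noise level, dBFS RMS.
#' @param snr Buzz peak level above `noise_level`, dB.
#' @param seed Integer master seed; fixes the whole scenario.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(days = 2, start_date = "2023-04-22", site_id = "siteA",
                          n_devices = 4, base_rate = 30, t_opt = 22.5,
                          width = 5, rain_hours = NULL, diurnal_factor = 1.2,
                          noise_level = -40, snr = 20, seed = 1L) {
  stopifnot(days >= 1, n_devices >= 1, base_rate >= 0, width > 0,
            diurnal_factor >= 0)
  structure(list(days = days, start_date = as.Date(start_date),
                 site_id = site_id, n_devices = n_devices,
                 base_rate = base_rate, t_opt = t_opt, width = width,
                 rain_hours = rain_hours, diurnal_factor = diurnal_factor,
                 noise_level = noise_level, snr = snr, seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Synthetic hourly temperature series
#'
#' A smooth diurnal cycle: minimum at 05:00, maximum at 14:00, sinusoidal in
#' between, plus small day-to-day drift. Serves as a stand-in temperature
#' logger for scenarios; real logger data can be supplied instead as a
#' data.frame with the same columns.
#'
#' @param spec A [scenario_spec()].
#' @param t_min,t_max Daily temperature extremes, deg C.
#' @return A data.frame `site_id, hour_start (POSIXct), temperature`.
#' @export
synth_temperatures <- function(spec, t_min = 12, t_max = 28) {
  hours <- seq(as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC"),
               by = "1 hour", length.out = spec$days * 24L)
  h <- as.numeric(format(hours, "%H"))
  # piecewise-cosine day: rise 05:00 -> 14:00, fall 14:00 -> 05:00 next day
  up <- h >= 5 & h < 14
  frac <- ifelse(up, (h - 5) / 9, ((h + 24 - 14) %% 24) / 15)
  temp <- ifelse(up,
                 t_min + (t_max - t_min) * (1 - cospi(frac)) / 2,
                 t_max - (t_max - t_min) * (1 - cospi(frac)) / 2)
  data.frame(site_id = spec$site_id, hour_start = hours, temperature = temp)
}

#' Hourly true buzz rate of a scenario
#'
#' @param spec A [scenario_spec()].
#' @param temps Temperature series (`site_id, hour_start, temperature`).
#' @return A data.frame `hour_start, temperature, rate` (events/h).
#' @export
scenario_rates <- function(spec, temps) {
  stopifnot(all(c("hour_start", "temperature") %in% names(temps)))
  h <- as.numeric(format(temps$hour_start, "%H"))
  rate <- spec$base_rate *
    exp(-(temps$temperature - spec$t_opt)^2 / (2 * spec$width^2)) *
    ifelse(h >= 6 & h < 21, spec$diurnal_factor, 1)
  if (!is.null(spec$rain_hours))
    rate[temps$hour_start %in% spec$rain_hours] <- 0
  data.frame(hour_start = temps$hour_start, temperature = temps$temperature,
             rate = rate)
}

#' Draw ground-truth event times for a scenario
#'
#' Events are sampled per device from independent Poisson processes with the
#' hourly rates of [scenario_rates()] (piecewise-constant per hour: a
#' Poisson count per hour, times uniform within the hour). Each device uses
#' its own RNG stream derived from `(seed, device index)`, so adding devices
#' never changes existing ones. Every ground-truth event gets a randomly
#' drawn fundamental frequency in 100-600 Hz.
#'
#' @param spec A [scenario_spec()].
#' @param temps Temperature series covering the scenario days.
#' @return A list with `events` (data.frame `device_id, site_id, event_time,
#'   f0_hz, duration_s`) and `rates` (the [scenario_rates()] table).
#' @export
sample_event_times <- function(spec, temps = synth_temperatures(spec)) {
  rates <- scenario_rates(spec, temps)
  need <- seq(as.POSIXct(paste(spec$start_date, "00:00:00"), tz = "UTC"),
              by = "1 hour", length.out = spec$days * 24L)
  if (!all(need %in% rates$hour_start))
    stop("temperature series does not cover all scenario hours")
  rows <- list()
  for (d in seq_len(spec$n_devices)) {
    dev <- sprintf("%s-dev%02d", spec$site_id, d)
    rows[[d]] <- local_rng(device_seed(spec$seed, d), function() {
      counts <- stats::rpois(nrow(rates), rates$rate)
      n <- sum(counts)
      if (n == 0L) return(NULL)
      t0 <- rep(as.numeric(rates$hour_start), counts)
      data.frame(device_id = dev, site_id = spec$site_id,
                 event_time = .POSIXct(t0 + stats::runif(n, 0, 3600), tz = "UTC"),
                 f0_hz = stats::runif(n, 100, 600),
                 duration_s = stats::runif(n, 0.3, 0.8))
    })
  }
  ev <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(ev))
    ev <- data.frame(device_id = character(0), site_id = character(0),
                     event_time = .POSIXct(numeric(0), tz = "UTC"),
                     f0_hz = numeric(0), duration_s = numeric(0))
  ev <- ev[order(ev$device_id, ev$event_time), ]
  rownames(ev) <- NULL
  list(events = ev, rates = rates)
}

#' Render a scenario to WAV files plus manifest and ground truth
#'
#' Writes one 16-bit mono WAV per schedule on-window per device: white
#' background noise at `spec$noise_level` dBFS RMS plus every ground-truth
#' buzz whose onset falls inside the window, rendered at `spec$snr` dB above
#' the noise. Events falling in off-windows are not rendered — they exist
#' only in the ground truth; this is exactly the sampling loss the duty
#' cycle model accounts for. Overlapping buzzes are summed.
#'
#' @param gt Ground truth from [sample_event_times()].
#' @param spec The [scenario_spec()].
#' @param sched A [duty_cycle_schedule()].
#' @param out_dir Output directory (created if needed).
#' @param sample_rate Rendering sample rate, Hz.
#' @param days Optionally restrict rendering to the first `days` days.
#' @return The manifest data.frame (also written to `manifest.csv`, with the
#'   ground truth in `ground_truth.csv`, in `out_dir`).
#' @export
render_scenario <- function(gt, spec, sched = duty_cycle_schedule(),
                            out_dir, sample_rate = 8000, days = spec$days) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  noise_sd <- 10^(spec$noise_level / 20)
  buzz_amp_db <- spec$noise_level + spec$snr
  dates <- spec$start_date + seq_len(days) - 1L
  windows <- do.call(rbind, lapply(dates, function(d) on_windows(sched, d)))
  devs <- unique(c(sprintf("%s-dev%02d", spec$site_id, seq_len(spec$n_devices))))
  man <- list()
  for (di in seq_along(devs)) {
    dev_ev <- gt$events[gt$events$device_id == devs[di], , drop = FALSE]
    for (wi in seq_len(nrow(windows))) {
      ws <- windows$start[wi]; we <- windows$end[wi]
      n <- as.integer(round(as.numeric(we - ws, units = "secs") * sample_rate))
      wseed <- (device_seed(spec$seed, di) + wi * 131) %% 2147483629
      x <- local_rng(wseed, function() stats::rnorm(n, 0, noise_sd))
      sel <- dev_ev[dev_ev$event_time >= ws & dev_ev$event_time < we, , drop = FALSE]
      for (ei in seq_len(nrow(sel))) {
        bs <- buzz_spec(f0 = sel$f0_hz[ei], duration = sel$duration_s[ei],
                        amplitude = buzz_amp_db)
        b <- synth_buzz(bs, sample_rate, seed = (wseed + ei) %% 2147483629)
        i0 <- as.integer(round(as.numeric(sel$event_time[ei] - ws,
                                          units = "secs") * sample_rate)) + 1L
        i1 <- min(n, i0 + length(b) - 1L)
        x[i0:i1] <- x[i0:i1] + b[seq_len(i1 - i0 + 1L)]
      }
      fn <- sprintf("%s_%s.wav", devs[di], format(ws, "%Y%m%dT%H%M%S"))
      rec <- audio_recording(pmin(1, pmax(-1, x)), sample_rate,
                             start_time = ws, device_id = devs[di],
                             site_id = spec$site_id)
      write_wav(rec, file.path(out_dir, fn))
      man[[length(man) + 1L]] <- data.frame(
        path = fn, device_id = devs[di], site_id = spec$site_id,
        start_time = format(ws, "%Y-%m-%dT%H:%M:%S"))
    }
  }
  manifest <- do.call(rbind, man)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  gt_out <- gt$events
  gt_out$event_time <- format(gt_out$event_time, "%Y-%m-%dT%H:%M:%S")
  utils::write.csv(gt_out, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
  manifest
}

#' One synthetic test recording: noise plus well-separated buzzes
#'
#' Convenience generator used throughout the test-suite and examples:
#' `duration` seconds of white noise at `noise_level` dBFS with `n_buzzes`
#' evenly spaced harmonic buzzes at `snr` dB above it.
#'
#' @param n_buzzes Number of injected buzzes.
#' @param duration Total length, seconds.
#' @param f0 Fundamental(s), recycled across buzzes.
#' @param snr Buzz peak over noise level, dB.
#' @param noise_level Noise RMS level, dBFS.
#' @param buzz_duration Single buzz length, seconds.
#' @param sample_rate Hz.
#' @param seed Integer seed.
#' @return A list: the [audio_recording] in `$rec`, true onset times in
#'   `$onsets`.
#' @export
synth_scenario_recording <- function(n_buzzes = 5, duration = 30, f0 = 220,
                                     snr = 20, noise_level = -40,
                                     buzz_duration = 0.5, sample_rate = 8000,
                                     seed = 1L) {
  n <- as.integer(duration * sample_rate)
  noise_sd <- 10^(noise_level / 20)
  x <- local_rng(seed, function() stats::rnorm(n, 0, noise_sd))
  f0 <- rep_len(f0, max(n_buzzes, 1L))
  onsets <- numeric(0)
  if (n_buzzes > 0) {
    gap <- duration / n_buzzes
    onsets <- (seq_len(n_buzzes) - 0.5) * gap
    for (i in seq_len(n_buzzes)) {
      bs <- buzz_spec(f0 = f0[i], duration = buzz_duration,
                      amplitude = noise_level + snr)
      b <- synth_buzz(bs, sample_rate, seed = seed + i)
      i0 <- as.integer(round(onsets[i] * sample_rate)) + 1L
      i1 <- min(n, i0 + length(b) - 1L)
      x[i0:i1] <- x[i0:i1] + b[seq_len(i1 - i0 + 1L)]
    }
  }
  list(rec = audio_recording(pmin(1, pmax(-1, x)), sample_rate), onsets = onsets)
}
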