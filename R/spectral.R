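#' Band-limited power spectra at fixed frequency resolution
#'
#' Splits a recording into Hann-tapered windows of `N = round(sample_rate /
#' bin_width)` samples (so the DFT bin spacing equals `bin_width`, 5 Hz by
#' default), computes the one-sided power spectrum of each window in dB
#' relative to full scale, and truncates it to the analysis band
#' (4 Hz - 3 kHz by default). All downstream detection thresholds are
#' relative to the per-frame noise floor, so the absolute dB reference is
#' immaterial: results are invariant under global gain scaling.
#'
#' @param rec An [audio_recording] with `sample_rate >= 2 * band[2]`.
#' @param bin_width Frequency resolution in Hz.
#' @param band Numeric `c(low, high)` analysis band in Hz.
#' @param hop_fraction Hop between successive windows as a fraction of the
#'   window length (0.5 = 50\% overlap).
#' @return A list of `spectral_frame` objects, each with fields
#'   `time_offset` (s), `freqs` (Hz, strictly increasing, spaced by
#'   `bin_width`), `power` (dB), `bin_width`, and `window_seconds`.
#' @examples
#' rec <- audio_recording(0.5 * sin(2 * pi * 200 * seq(0, 1, by = 1/8000)), 8000)
#' fr <- compute_frames(rec)
#' fr[[1]]$freqs[which.max(fr[[1]]$power)]  # 200
#' @export
compute_frames <- function(rec, bin_width = 5, band = c(4, 3000),
                           hop_fraction = 0.5) {
  stopifnot(inherits(rec, "audio_recording"), bin_width > 0,
            length(band) == 2L, band[1] < band[2], hop_fraction > 0)
  if (rec$sample_rate < 2 * band[2])
    stop("sample_rate below Nyquist requirement for band: need >= ", 2 * band[2], " Hz")
  n <- as.integer(round(rec$sample_rate / bin_width))
  win_s <- n / rec$sample_rate
  frames <- frame_windows(rec, win_s, hop_fraction * win_s)
  w <- hann_window(n)
  wsum <- sum(w)
  k <- 0:(n %/% 2L)
  freqs <- k * bin_width
  keep <- freqs >= band[1] & freqs <= band[2]
  lapply(frames, function(f) {
    X <- stats::fft(f$samples * w)[k + 1L]
    # one-sided amplitude-squared spectrum: a bin-aligned unit sine -> 0 dB
    p <- (2 * Mod(X) / wsum)^2
    structure(
      list(time_offset = f$offset, freqs = freqs[keep],
           power = 10 * log10(p[keep] + 1e-20), bin_width = bin_width,
           window_seconds = win_s),
      class = "spectral_frame"
    )
  })
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / n)

#' Per-frame noise floor
#'
#' The median in-band power (dB) of a frame; robust as long as fewer than
#' half the bins carry signal, which holds for harmonic buzzes against the
#' 600-bin analysis band.
#'
#' @param frame A `spectral_frame`.
#' @return Noise-floor level in dB.
#' @export
noise_floor <- function(frame) {
  stopifnot(inherits(frame, "spectral_frame"), length(frame$power) > 0L)
  stats::median(frame$power)
}

#' Export a spectrogram matrix for diagnostics
#'
#' Writes the time-frequency dB matrix to CSV: first column the frequency
#' bin centres (Hz), one column per frame, header row giving each frame's
#' time offset in seconds. The dynamic range is clipped at 70 dB below the
#' matrix maximum, mirroring typical spectrogram display settings.
#'
#' @param frames Output of [compute_frames()] (at least one frame).
#' @param path Output CSV path.
#' @param dynamic_range_db Clip floor below the maximum, in dB.
#' @return Invisibly, the clipped matrix (bins x frames).
#' @export
export_spectrogram <- function(frames, path, dynamic_range_db = 70) {
  stopifnot(length(frames) >= 1L)
  mat <- vapply(frames, function(f) f$power, numeric(length(frames[[1]]$power)))
  mat <- matrix(mat, nrow = length(frames[[1]]$power))
  mat <- pmax(mat, max(mat) - dynamic_range_db)
  out <- data.frame(freq_hz = frames[[1]]$freqs, mat, check.names = FALSE)
  names(out)[-1] <- sprintf("%.4f", vapply(frames, `[[`, 0, "time_offset"))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(mat)
}
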