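#' Audio recordings
#'
#' An `audio_recording` carries a mono waveform normalised to \[-1, 1\], its
#' sample rate, the wall-clock start time of the recording, and device/site
#' tags used downstream when detections are aggregated into activity series.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\]. All values must
#'   be finite.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Start of the recording, a `POSIXct` (naive local civil
#'   time; the package does no timezone arithmetic) or a string parseable by
#'   [as.POSIXct()].
#' @param device_id,site_id Character tags; `device_id` must be non-empty.
#' @return An object of class `audio_recording`.
#' @examples
#' rec <- audio_recording(sin(2 * pi * 220 * seq(0, 1, by = 1/8000)), 8000)
#' duration_seconds(rec)
#' @export
audio_recording <- function(samples, sample_rate,
                            start_time = as.POSIXct("2023-04-15 06:00:00", tz = "UTC"),
                            device_id = "dev0", site_id = "siteA") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("zero-length audio")
  if (!all(is.finite(samples))) stop("samples must all be finite")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  if (!nzchar(device_id)) stop("device_id must be non-empty")
  start_time <- parse_iso_time(start_time)
  structure(
    list(samples = samples, sample_rate = as.numeric(sample_rate),
         start_time = start_time, device_id = device_id, site_id = site_id),
    class = "audio_recording"
  )
}

#' @rdname audio_recording
#' @param rec An `audio_recording`.
#' @export
duration_seconds <- function(rec) length(rec$samples) / rec$sample_rate

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %s/%s  %.3f s @ %g Hz, start %s\n",
              x$site_id, x$device_id, duration_seconds(x), x$sample_rate,
              format(x$start_time, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

# --- WAV I/O ----------------------------------------------------------------
# Minimal RIFF/WAVE PCM reader/writer. No audio package ships with the target
# environment, so the container format is parsed here directly; only
# uncompressed integer PCM (format tag 1) is supported.

#' Read a PCM WAV file
#'
#' Reads an uncompressed PCM RIFF/WAVE file into an [audio_recording].
#' Samples are rescaled to \[-1, 1\]. Multi-channel files are averaged to
#' mono with a warning; 8/16/24/32-bit integer PCM are accepted.
#'
#' @param path Path to a WAV file.
#' @inheritParams audio_recording
#' @return An [audio_recording].
#' @export
read_wav <- function(path, start_time = as.POSIXct("2023-04-15 06:00:00", tz = "UTC"),
                     device_id = "dev0", site_id = "siteA") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", sz)
      fmt <- list(
        tag       = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels  = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        rate      = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits      = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk)")
  if (fmt$tag != 1L) stop("unsupported WAV encoding (only integer PCM, format tag 1)")
  bytes <- fmt$bits %/% 8L
  n <- length(data_raw) %/% bytes
  if (n == 0L) stop("zero-length audio")
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n, 1, signed = FALSE)) - 128) / 128,
    "16" = as.numeric(readBin(data_raw, "integer", n, 2, signed = TRUE,
                              endian = "little")) / 32768,
    "24" = {
      m <- matrix(as.integer(data_raw[seq_len(n * 3L)]), nrow = 3L)
      v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    "32" = as.numeric(readBin(data_raw, "integer", n, 4, signed = TRUE,
                              endian = "little")) / 2147483648,
    stop("unsupported PCM bit depth: ", fmt$bits)
  )
  if (fmt$bits != 16L) warning("converted ", fmt$bits, "-bit PCM on read")
  if (fmt$channels > 1L) {
    warning("averaged ", fmt$channels, " channels to mono")
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_recording(x, fmt$rate, start_time = start_time,
                  device_id = device_id, site_id = site_id)
}

#' Write an audio recording as 16-bit PCM mono WAV
#'
#' Samples outside \[-1, 1\] are clipped with a warning. [read_wav()]
#' inverts the file up to one 16-bit quantisation step (2^-15).
#'
#' @param rec An [audio_recording].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- rec$samples
  if (any(x > 1 | x < -1)) {
    warning("samples outside [-1, 1] clipped on write")
    x <- pmin(1, pmax(-1, x))
  }
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")          # PCM, mono
  fs <- as.integer(round(rec$sample_rate))
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")            # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")         # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Slice a recording into fixed-length analysis windows
#'
#' Frames are `window_seconds` long, advanced by `hop_seconds`; a trailing
#' partial window is dropped. The frame count equals
#' `floor((duration - window) / hop) + 1`.
#'
#' @param rec An [audio_recording].
#' @param window_seconds,hop_seconds Window length and hop, in seconds.
#' @return A list of frames, each `list(offset = <seconds>, samples = <vector>)`.
#' @export
frame_windows <- function(rec, window_seconds, hop_seconds) {
  stopifnot(inherits(rec, "audio_recording"), hop_seconds > 0)
  w <- as.integer(round(window_seconds * rec$sample_rate))
  h <- as.integer(round(hop_seconds * rec$sample_rate))
  n <- length(rec$samples)
  if (w > n) stop("recording shorter than one analysis window")
  starts <- seq.int(1L, n - w + 1L, by = h)
  lapply(starts, function(s) list(
    offset = (s - 1L) / rec$sample_rate,
    samples = rec$samples[s:(s + w - 1L)]
  ))
}

#' Read a recording manifest
#'
#' A manifest is a CSV with header `path,device_id,site_id,start_time`
#' (ISO 8601 local time). Paths are interpreted relative to the manifest's
#' own directory unless absolute.
#'
#' @param path Manifest CSV path.
#' @return A data.frame with columns `path`, `device_id`, `site_id`,
#'   `start_time` (`POSIXct`).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "device_id", "site_id", "start_time")
  if (!all(need %in% names(m))) stop("manifest must have columns: ",
                                     paste(need, collapse = ", "))
  if (nrow(m) == 0L) stop("empty manifest")
  if (anyDuplicated(m$path)) stop("duplicate paths in manifest")
  if (any(!nzchar(m$device_id))) stop("device_id must be non-empty")
  m$start_time <- parse_iso_time(m$start_time)
  if (any(is.na(m$start_time))) stop("unparseable start_time in manifest")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m[need]
}

# ISO 8601 local timestamps, with either "T" or space as the separator.
# base as.POSIXct silently parses "2023-04-22T07:00:00" as date-only,
# truncating the time to midnight, so normalise the separator first.
parse_iso_time <- function(x) {
  if (is.character(x) || is.factor(x))
    x <- as.POSIXct(sub("T", " ", as.character(x)), tz = "UTC")
  x
}
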