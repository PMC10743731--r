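test_that("find_peaks: flat spectrum, lone spike, and exhaustive-scan oracle", {
  mk_frame <- function(power) structure(
    list(freqs = seq(5, length.out = length(power), by = 5), power = power,
         bin_width = 5, window_seconds = 0.2), class = "spectral_frame")

  expect_equal(nrow(find_peaks(mk_frame(rep(-60, 100)), 10)), 0L)

  p <- rep(-60, 100); p[40] <- -30
  pk <- find_peaks(mk_frame(p), 10)
  expect_equal(pk$freq, 200)  # bin 40 at 5 Hz spacing
  expect_equal(pk$power, -30)

  set.seed(101)
  for (i in 1:100) {
    power <- -60 + stats::rnorm(200, 0, 4)
    power[sample(200, 5)] <- power[sample(200, 5)] + runif(5, 5, 30)
    fr <- mk_frame(power)
    got <- find_peaks(fr, 8)
    exp <- oracle_find_peaks(fr$freqs, fr$power, 8)
    expect_equal(got, exp, ignore_attr = TRUE)
  }
})

test_that("classify_frame accepts harmonic stacks and rejects lone tones", {
  fs <- 8000
  buzz <- synth_buzz(buzz_spec(f0 = 220, n_harmonics = 3, amplitude = -20),
                     fs, seed = 2)
  x <- buzz[1:1600] + stats::rnorm(1600, 0, 10^(-40 / 20))
  fr <- compute_frames(audio_recording(x, fs))[[1]]
  cand <- classify_frame(fr, detector_config())
  expect_false(is.null(cand))
  expect_lt(abs(cand$f0 - 220), 5 + 1e-9)  # one-bin tolerance
  expect_gte(cand$n_harmonics, 2)

  tone <- 0.1 * sin(2 * pi * 200 * (0:1599) / fs) + stats::rnorm(1600, 0, 1e-4)
  fr2 <- compute_frames(audio_recording(tone, fs))[[1]]
  expect_null(classify_frame(fr2, detector_config()))

  silence <- audio_recording(stats::rnorm(1600, 0, 1e-5), fs)
  expect_null(classify_frame(compute_frames(silence)[[1]], detector_config()))
})

test_that("classify_frame prefers the true f0 over a louder 2nd harmonic", {
  fs <- 8000
  t <- (0:1599) / fs
  # harmonic stack where the 2nd partial is the loudest
  x <- 0.05 * sin(2 * pi * 150 * t) + 0.12 * sin(2 * pi * 300 * t) +
    0.04 * sin(2 * pi * 450 * t) + 0.03 * sin(2 * pi * 600 * t) +
    stats::rnorm(1600, 0, 1e-4)
  cand <- classify_frame(compute_frames(audio_recording(x, fs))[[1]],
                         detector_config())
  expect_false(is.null(cand))
  expect_lt(abs(cand$f0 - 150), 5 + 1e-9)
})

test_that("segment_events implements the stated grouping rules", {
  cfg <- detector_config(min_event_frames = 2, max_gap_frames = 1)
  mk <- function(i, f0) list(time_offset = i * 0.1, f0 = f0,
                             n_harmonics = 2, snr = 20)
  # frames 0..9; candidates at 3,4,5 with stable f0 -> one 3-frame event
  cands <- rep(list(NULL), 10)
  for (i in 3:5) cands[[i + 1]] <- mk(i, 220)
  ev <- segment_events(cands, cfg, 0.2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 3L)
  expect_equal(ev$start, 0.3)
  expect_equal(ev$end, 0.5 + 0.2)

  # candidates at 3,4 then 6,7 with a 1-frame gap -> merged
  cands <- rep(list(NULL), 10)
  for (i in c(3, 4, 6, 7)) cands[[i + 1]] <- mk(i, 220)
  ev <- segment_events(cands, cfg, 0.2)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$n_frames, 4L)

  # f0 jump beyond tracking tolerance splits the run
  cands <- rep(list(NULL), 10)
  for (i in 2:4) cands[[i + 1]] <- mk(i, 220)
  for (i in 5:7) cands[[i + 1]] <- mk(i, 400)
  ev <- segment_events(cands, cfg, 0.2)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$f0_median, c(220, 400))

  # runs shorter than min_event_frames are discarded
  cands <- rep(list(NULL), 10)
  cands[[4]] <- mk(3, 220)
  expect_equal(nrow(segment_events(cands, cfg, 0.2)), 0L)
})

test_that("segment_events equals the brute-force grouping oracle", {
  cfg <- detector_config()
  set.seed(77)
  for (trial in 1:100) {
    cands <- random_candidates(sample(10:60, 1))
    got <- segment_events(cands, cfg, 0.2)
    exp <- oracle_segment(cands, cfg, 0.2)
    expect_equal(got, exp, ignore_attr = TRUE)
  }
})

test_that("count_buzzes finds injected buzzes and stays quiet on noise", {
  s <- synth_scenario_recording(n_buzzes = 5, duration = 60, snr = 20, seed = 21)
  res <- count_buzzes(s$rec)
  expect_equal(res$count, 5L)
  # detected onsets align with injected onsets
  expect_true(all(abs(sort(res$events$start) - s$onsets) < 0.5))

  noise <- synth_scenario_recording(n_buzzes = 0, duration = 60,
                                    noise_level = -30, seed = 22)
  expect_lte(count_buzzes(noise$rec)$count, 1L)
})

test_that("counts are deterministic and gain-invariant", {
  s <- synth_scenario_recording(n_buzzes = 3, duration = 20, seed = 31)
  r1 <- count_buzzes(s$rec)
  r2 <- count_buzzes(s$rec)
  expect_identical(r1, r2)
  for (g in c(0.25, 0.5, 2)) {
    x <- pmin(1, pmax(-1, s$rec$samples * g))
    rg <- count_buzzes(audio_recording(x, s$rec$sample_rate))
    expect_equal(rg$count, r1$count)
  }
})

test_that("detector config validation and JSON round trip", {
  expect_error(detector_config(min_harmonics = 0), "min_harmonics")
  expect_error(detector_config(f0_range = c(1000, 50)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(f0_range = c(80, 800), min_harmonics = 3),
                       path, auto_unbox = TRUE)
  cfg <- read_detector_config(path)
  expect_equal(cfg$f0_range, c(80, 800))
  expect_equal(cfg$min_harmonics, 3)
  expect_equal(cfg$peak_threshold, 10)  # default fills in
  jsonlite::write_json(list(bogus = 1), path, auto_unbox = TRUE)
  expect_error(read_detector_config(path), "unknown")
})
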