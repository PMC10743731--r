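# buzzcount

Passive acoustic monitoring (PAM) of flying insects: detect wingbeat
"buzz" events in audio, count them under a duty-cycled recording schedule,
and turn the counts into activity metrics comparable with traditional
surveys (hand netting, pan traps).

## Who this is for

Ecologists and engineers working with low-cost acoustic IoT sensors who need
an auditable, open reimplementation of the buzz-counting analysis chain:
field recordings in, `buzz/h` time series and survey correlations out. No
field data are required to validate an installation — the package ships a
synthetic-scenario generator with known ground truth.

## The method

A flying insect's wingbeat produces a harmonic sound: a fundamental
frequency *f₀* (the wingbeat rate, typically 50–1000 Hz) plus partials at
*k·f₀*. The detector works on band-limited (4 Hz–3 kHz) power spectra at
5 Hz resolution (Hann window of `fs / 5` samples, 50 % overlap):

1. **Peak picking** — local spectral maxima more than 10 dB above the
   frame's noise floor (the median in-band power, so detection is
   gain-invariant).
2. **Harmonic verification** — a frame is a buzz candidate if some peak with
   *f₀* ∈ [50, 1000] Hz is corroborated by ≥ 2 further peaks within 7.5 Hz
   of its integer multiples; the candidate maximising the harmonic count
   wins (ties by summed harmonic power).
3. **Event segmentation** — consecutive candidate frames whose *f₀* stays
   within 15 Hz of the running median are merged, gaps of one frame are
   bridged, and runs of ≥ 2 frames become events ("counts").

Devices record on a duty cycle — by default 12 min on / 48 min off from
06:00–21:00 and 4 min on / 56 min off overnight (216 recorded min/day) — so
raw counts are converted to a rate per hour of equivalent continuous
recording:

    buzz/h = count / recorded_minutes × 60

Aggregations: hourly means across a site's devices, temperature-binned
activity (mean ± SE per max-temperature band: `<15`, `15–20`, `20–25`,
`25–30`, `30+` °C), weekly daytime-vs-24 h comparison, and Pearson
correlation of site × period buzz rates against per-replicate survey counts.

## Worked example

```r
library(buzzcount)

# 30 s of white noise at -40 dBFS with five 220 Hz buzzes at 20 dB SNR
s <- synth_scenario_recording(n_buzzes = 5, duration = 30, f0 = 220,
                              snr = 20, seed = 2)
res <- count_buzzes(s$rec)
res$count
#> [1] 5
res$events
#>   start  end f0_median n_frames peak_snr
#> 1   2.9  3.6       220        6 42.87872
#> 2   8.9  9.6       220        6 41.63306
#> 3  14.9 15.6       220        6 41.22830
#> 4  20.9 21.6       220        6 40.91368
#> 5  26.9 27.6       220        6 43.49782
```

All five injected buzzes are recovered: each event spans 6 analysis frames
(≈ 0.7 s including the window tail), tracks the true 220 Hz fundamental, and
sits ~41–43 dB above the frame noise floor.

```r
sched <- duty_cycle_schedule()   # the default field regime
day0 <- as.POSIXct("2023-05-01 00:00:00", tz = "UTC")
recorded_minutes(sched, day0, day0 + 86400)
#> [1] 216
buzz_per_hour(6, 12)             # 6 counts in a 12-min on-window
#> [1] 30
```

216 min/day is the schedule's total recording budget; 6 events in one
12-minute window extrapolate to 30 buzz/h of continuous recording.

## Command line

```sh
Rscript inst/cli/buzz.R simulate --out demo/ --days 1 --devices 2 --seed 1
Rscript inst/cli/buzz.R batch demo/manifest.csv --out-events ev.csv --out-summary sum.csv
Rscript inst/cli/buzz.R aggregate ev.csv --out activity.csv
Rscript inst/cli/buzz.R correlate activity.csv surveys.csv periods.csv --method pan_trap
```

Exit codes: 0 success, 2 config/usage error, 3 data error.

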