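---
title: "Counting insect buzzes: models, parameters, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting insect buzzes: models, parameters, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(buzzcount)
```

## The problem

Traditional flying-insect surveys (sweep netting, pan traps) are
labour-intensive and sample only snapshots of activity. Acoustic sensors can
instead record continuously and count insect flybys from the sound their
wings make. This package implements that analysis chain: spectral buzz
detection, duty-cycle-aware rate estimation, and the activity metrics used
to compare acoustic counts with trap counts.

## Signal model and detector

A wingbeat signal is modelled as a harmonic stack: a fundamental $f_0$ (the
wingbeat rate) with partials at $k f_0$. Detection runs on short-time power
spectra:

* **Resolution.** The analysis window is $N = f_s / \Delta f$ samples with
  $\Delta f = 5$ Hz, giving DFT bins exactly 5 Hz apart (1600 samples =
  0.2 s at the default 8 kHz). A Hann taper bounds spectral leakage so that
  a bin-aligned sine keeps $\ge 90\%$ of its energy in its bin $\pm 1$;
  windows overlap 50 %.
* **Band.** Spectra are truncated to 4 Hz–3 kHz. The 4 Hz floor is honoured
  literally, but the fundamental search starts at 50 Hz: infrasound is not a
  plausible wingbeat rate, while harmonics up to 3 kHz still corroborate it.
* **Gain invariance.** Power is expressed in dB relative to full scale, but
  every detection threshold is relative to the frame's noise floor, defined
  as the **median** in-band power — robust while signal occupies under half
  of the 600 bins. Scaling the waveform by any positive constant leaves
  detections unchanged (a property the test suite checks directly).
* **Classification.** Peaks are strict local maxima more than
  `peak_threshold` dB above the floor. Each peak inside `f0_range` is scored
  by how many peaks lie within `harmonic_tol` of its multiples $k f_0$;
  the highest harmonic count wins, with ties broken by summed harmonic
  power. Scoring by harmonic count rather than peak height prevents locking
  onto a dominant second harmonic (tested with a stack whose 2nd partial is
  loudest).
* **Segmentation.** Candidate frames merge while their $f_0$ stays within
  `f0_track_tol` of the running median; up to `max_gap_frames` silent frames
  are bridged; runs shorter than `min_event_frames` are dropped. The event
  end extends one window length past the last frame onset.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `bin_width` | 5 | Hz | stated device resolution; fixes the window length |
| `f0_range` | 50–1000 | Hz | wingbeat fundamentals of bees, flies, grasshoppers |
| `peak_threshold` | 10 | dB | keeps stationary-noise false alarms ≤ 1 / 10 min |
| `min_harmonics` | 2 | – | one harmonic alone is too easy to fake with noise |
| `harmonic_tol` | 7.5 | Hz | 1.5 bins: one bin of quantisation + tracking slack |
| `min_event_frames` | 2 | frames | 0.2 s at 50 % overlap, a plausible minimum flyby |
| `max_gap_frames` | 1 | frames | bridges single-frame dropouts in one pass |
| `f0_track_tol` | 15 | Hz | wingbeat modulation within one pass |

The source device's thresholds are proprietary and unpublished; these values
are this package's own operationalisation, chosen once to meet the recall
(≥ 0.95 at SNR ≥ 15 dB) and false-positive (≤ 1 / 10 min of noise)
properties, then frozen. They are all exposed through `detector_config()`
and its JSON reader, not hard-coded.

## Duty cycle and rate estimation

The default `duty_cycle_schedule()` records 12 min on / 48 min off between
06:00 and 21:00 (20 %) and 4 min on / 56 min off overnight (1/15 ≈ 6.7 %,
sometimes quoted rounded as 7 %), totalling exactly 216 min/day. Cycle phase
anchors at each period start ("on" first); on-windows are half-open
$[start, end)$, so an instant exactly on a boundary belongs to the later
state. The night period wraps midnight; callers never see the internal
split.

Counts from recorded minutes $m$ convert to a rate per hour of equivalent
continuous recording, $\widehat{\lambda} = 60\,c/m$; hours with $m = 0$ are
*missing*, never zero. For events arriving as a Poisson process thinned by
the schedule, $c \sim \mathrm{Pois}(\lambda m / 60)$, so
$\widehat{\lambda}$ is unbiased — verified by simulation at
$\lambda \in \{5, 30, 120\}$ events/h over 200 days (within 3 SE).

## Aggregation choices

* **Survey comparison window** is 10:00–16:00, the slot in which netting and
  pan-trap sessions run, exposed as `window_hours`.
* **Temperature bins** use the hour's maximum reading, left-closed
  right-open edges at 15/20/25/30 °C with an open top bin; readings below
  the first edge fall into an explicit `<15` bin rather than being dropped
  silently. Edge membership (20 °C → "20–25") is a convention the data do
  not dictate; it is documented and tested.
* **SE** is the sample standard deviation ($n-1$) over $\sqrt n$.
* **Pearson correlation** is computed from the product-moment formula with a
  two-sided $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df (checked against
  `cor.test`). Constant vectors are an error, not a silent `NA`.
* Site × period rates aggregate across a site's devices *before*
  correlating, since device-to-trap replicate pairing is not meaningful.
* Other hypothesis tests (Kruskal–Wallis, ANOVA/Tukey, Mann–Whitney, KS) are
  deliberately left to base R — they are glue, not method.

## The synthetic world

`scenario_spec()` states the simulated world once:

* **Events**: per device, an inhomogeneous Poisson process, piecewise
  constant per hour, with rate
  $\lambda(t) = \lambda_0 \exp\!\big(-(T(t)-T_{opt})^2 / 2w^2\big) \cdot d(t)$,
  $T_{opt} = 22.5$ °C and $w = 5$ °C (peak activity in the 20–25 °C band,
  suppression above 30 °C, matching reported social-bee behaviour), a
  daytime factor $d = 1.2$ (diurnal excess of roughly 20 %), and rate forced
  to zero in rain hours.
* **Audio**: white background noise (default −40 dBFS RMS) plus harmonic
  buzzes at a stated SNR, 4 partials rolling off 6 dB per step, 0.3–0.8 s
  with linear attack/release. One RNG stream per device, derived from
  `(seed, device index)`, so adding a device never perturbs the others.
* **Capture**: events in off-windows exist only in the ground truth — that
  is precisely the sampling loss the schedule model accounts for.

What this emulates: harmonic structure, realistic rates, temperature and
rain response, duty-cycle thinning. What it does **not** emulate: wind and
machinery noise, overlapping simultaneous insects, species-specific timbre,
microphone directivity, clock drift. A green detector test therefore
establishes correct behaviour *under the stated signal model*, not field
accuracy; the original field validation (manual audit of recordings) cannot
be reproduced without the study audio, which was never deposited.

## Numerical notes and degenerate inputs

* dB conversion adds $10^{-20}$ to linear power, so silence maps to a finite
  floor instead of $-\infty$.
* WAV I/O is 16-bit PCM mono; the round trip is exact in sample count and
  within $2^{-15}$ in amplitude. Out-of-range samples clip with a warning.
  Multi-channel and non-16-bit PCM inputs convert on read with a warning.
* A recording shorter than one analysis window, an empty manifest, a
  constant vector passed to the correlation, and `recorded_minutes = 0` all
  fail loudly or flag missing rather than returning a guessable number.
* `pearson_r` clamps $|r|$ at 1 against floating-point excess before the
  $t$ transform.
* Timestamps are naive local civil time handled in a fixed-offset zone; the
  schedule is defined in local clock hours, so no DST arithmetic is applied
  anywhere.

## Known limitations

* Counts are flybys, not individuals: repeated passes of one insect count
  repeatedly (deduplication is unstated upstream and not attempted).
* Two buzzes closer than one hop with similar $f_0$ merge into one event;
  the recall criterion is stated for spacing ≥ 1 s for this reason.
* No taxon identification — the spectral signature alone does not support
  biodiversity estimation, and none is attempted.
* The detector is an operationalisation of a described-but-proprietary
  algorithm; counts are comparable in kind, not bit-identical to the
  commercial device.
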