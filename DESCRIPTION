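Package: buzzcount
Title: Passive Acoustic Monitoring of Flying Insects by Buzz Counting
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and counts insect wingbeat ("buzz") events in mono PCM
    WAV recordings by harmonic spectral-pattern analysis, models duty-cycled
    recording schedules, and aggregates detections into activity metrics
    (buzz per hour, hourly and temperature-binned activity, correlations
    with traditional trap surveys). Includes a synthetic-scenario generator
    with known ground truth (harmonic buzz synthesis over noise,
    temperature-driven inhomogeneous Poisson event times) so the full
    pipeline is testable without field recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
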