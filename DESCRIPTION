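Package: spindlepipe
Title: Rodent Sleep Staging, Sleep-Spindle Detection and Behavioural Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico replica of a rodent polysomnography study pipeline:
    synthesis of three-state (wake/NREM/REM) EEG+EMG recordings with injected
    sigma-band spindle bursts and ground-truth annotations; band filtering and
    fixed-length epoching; exemplar-trained k-nearest-neighbour sleep staging;
    spectrogram-based sigma-band (12-20 Hz) spindle detection with 0.5-2 s
    duration criteria and event characterisation (RMS amplitude, power-weighted
    mean frequency, density per NREM minute); cold-allodynia and elevated-plus-
    maze behavioural scoring; and normality-gated within/between-group
    comparison statistics with mean +/- SEM summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite,
    knitr,
    withr
Config/testthat/edition: 3
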