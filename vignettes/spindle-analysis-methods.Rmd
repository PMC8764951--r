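---
title: "Methods: synthetic polysomnography, staging, spindle detection and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic polysomnography, staging, spindle detection and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlepipe)
```

This vignette is the package's own account of its models and numerical
choices: what the synthetic generator emulates, how the stager and the
spindle detector work, which parameters matter and why their defaults were
chosen, and what the passing test suite does and does not establish about
real recordings.

## The synthetic generator

`synthesize_recording()` produces one animal-session of EEG+EMG with ground
truth. Its parts:

**Vigilance states.** A first-order Markov chain over WAKE/NREM/REM at the
5-s epoch scale, started in WAKE. The default transition matrix gives
minutes-long wake and NREM bouts, shorter REM bouts and no direct
WAKE-to-REM transitions — the bout structure of a morning rat recording.
Group-by-session effects on sleep architecture are applied by multiplying
the columns into REM and NREM by a modifier and renormalising rows, which
shifts the stationary distribution without inventing new dynamics.

**EEG.** Each state contributes fixed sinusoidal oscillators (wake:
low-voltage 8 and 25 Hz; NREM: high-amplitude 1.5 Hz delta; REM: 7 Hz
theta) gated by the state mask over a continuous time base, plus a 1/f
noise floor built by spectral shaping of white noise (power ∝ 1/f, floored
at 0.5 Hz, unit-RMS, scaled per state). Spectral shaping was chosen over an
autoregressive fit because it gives an exactly controllable floor with no
fitting step.

**Spindles.** A homogeneous Poisson process within each contiguous NREM
span, at the configured rate (events per NREM minute, times the
group-session modifier), with overlap-rejected placement, durations drawn
uniformly from 0.5–3 s and carrier frequencies uniformly from 9–15 Hz —
the canonical spindle ranges. Each burst is an amplitude-enveloped
sinusoid with a raised-cosine (Hann) envelope: zero at both edges, peaking
mid-burst. The raised cosine matches the waxing-and-waning morphology and
has a closed-form energy, which the tests exploit.

**EMG.** White noise scaled to the state's RMS tone (wake 60, NREM 15,
REM 4 µV): high tone awake, atonia in REM.

**Behaviour.** Five Bernoulli withdrawal trials per animal at a
group-by-day probability, and a 300-s elevated-plus-maze session as an
alternating center/arm renewal process with exponential dwells at
group-by-day means.

Defaults are chosen once to represent the study conditions: 3000 Hz
acquisition, 5-s epochs, 150-min sessions, spindle rate 2 per NREM minute
(a typical rodent density), burst amplitude 80 µV against a 15–25 µV noise
floor. The emulated study reports its group effects only as figure-level
mean ± SEM bars with significance stars, so the group-effect magnitudes here
are package choices that reproduce the reported *directions*: the
Valerian-treated group carries a higher spindle rate and a higher baseline
REM propensity declining across sessions, with NREM rising by day 6; the
untreated neuropathic group has elevated withdrawal probability (sham zero,
treated zero by day 6) and longer closed-arm dwell on day 6.

**What the generator does not emulate:** K-complexes and other NREM
grapho-elements, movement artifacts, electrode drift, circadian
non-stationarity, or inter-animal spectral variability. Tests passing
against this generator therefore establish the *pipeline's* correctness
(recovery of known ground truth under the stated physics), not staging or
detection accuracy on real rat EEG.

## Staging

The stager follows the semi-automatic scheme: state-typical exemplar
segments (≥ 30 s each, all three states required, enforced at fit time) are
cut into 5-s epochs and a KNN classifier is fitted on per-epoch features.
The feature set is a package choice — the scheme it implements specifies
only "similarity of EEG and EMG" — and uses the canonical state signatures:
log band powers (delta 0.5–4, theta 4–9, sigma 12–20, beta 20–30 Hz,
half-open bins), the theta/delta ratio, and EMG RMS, z-scored by training
statistics because the units are incommensurable. Band powers are scaled so
a unit-amplitude sinusoid contributes 1/2 regardless of epoch length or
sampling rate.

`k` defaults to 5 with majority vote. Distance ties and vote ties are both
broken by the fixed state order WAKE < NREM < REM, never by input order, so
predictions are permutation-invariant over exemplars (tested). No post-hoc
hypnogram smoothing is applied. Stage percentages are reported over the
whole recording by default, with a total-sleep denominator available
(`stage_percentages(..., "TOTAL_SLEEP")`); the default is total recording
because the emulated analysis does not state its denominator.

## Spindle detection

Detection follows the spectrogram-threshold procedure with explicit,
reproducible parameter choices:

- **Spectrogram:** Hann-tapered short-time periodogram, 1.0-s window,
  0.1-s step. One second is the shortest window giving 1-Hz bins across
  the 12–20 Hz band (needed for sharp band edges); 0.1 s keeps boundary
  quantisation well below the 0.5-s minimum duration. Power is a one-sided
  PSD whose integral over frequency recovers the tapered segment's mean
  power (Parseval, tested to 5% on white noise).
- **Band:** extended sigma, 12–20 Hz, both edges *inclusive*.
- **Threshold:** mean + `k_sd` × SD of sigma power over NREM-aligned bins,
  `k_sd = 2.5`, with the population (divide-by-n) SD convention
  (documented and tested against hand computation). The procedure being
  reproduced tuned its threshold against visual identification without
  reporting a value; an explicit data-adaptive rule replaces that, and an
  absolute `threshold` override is available everywhere.
- **Runs and merging:** maximal supra-threshold runs, with runs separated
  by less than `merge_gap = 0.3` s merged, so envelope dips do not split
  one spindle.
- **Duration criterion:** 0.5–2 s; events must have their midpoint inside
  a NREM epoch (spindles are NREM phenomena; detections elsewhere are
  artifacts by definition here).

**Boundary refinement.** Run widths on a 1-s-window spectrogram smear the
true burst duration by up to the window length, so sub-window durations are
indistinguishable from it (0.4-s and 0.5-s bursts yield nearly identical
run widths). Event boundaries are therefore refined against the raw EEG:
the sigma-band zero-phase Butterworth (order 2) analytic-signal amplitude
envelope, smoothed by a 0.1-s moving average, is thresholded at 40% of the
event's own peak; the crossing width is converted to a duration by the
closed-form raised-cosine shape factor 1 − (2/π)·asin(√0.4), minus a fixed
0.07-s allowance for filter-transient broadening. Both constants were
calibrated once on noiseless synthetic bursts of known duration and then
frozen; with them, injected durations 0.1–3.0 s are accepted exactly on the
0.5–2 s window (tested). The relative-to-peak rule makes the duration
estimate amplitude-invariant; the raised-cosine shape factor is exact for
the generator's envelope and approximate for other waxing-waning shapes.

**Spectral-peak validation.** A 1-s Hann window leaks roughly a quarter of
an 11-Hz burst's peak power into the 12-Hz bin, so threshold crossing alone
cannot give inclusive-exact band edges. Each candidate is validated by the
dominant frequency of its zero-padded (4×) periodogram, searched within the
detection band widened by a 5-Hz guard (the guard keeps the search away
from the large delta background), and kept only if that peak lies within
the band to half a resolution bin (0.5/duration Hz). With this rule, swept
integer-frequency bursts are detected exactly for 12–20 Hz (tested).

**Characterisation.** Per event: RMS amplitude over the half-open interval;
power-weighted mean frequency over in-band periodogram components (an
event with negligible in-band power yields `NA`; a full-spectrum option
exists via `band = NULL`); peak sigma power; and, per recording, density =
events per NREM minute.

**Recovery metrics.** The generator draws carriers from 9–15 Hz and
durations from 0.5–3 s, while the detector is hard-limited to 12–20 Hz and
0.5–2 s; events outside the detector's own passband or duration window are
undetectable *by design*, not by defect. Recall is therefore computed over
detectable ground truth (carrier in band, duration within the window), and
precision against all ground truth, with ≥ 50% interval-overlap matching.
The density-recovery check uses a generator configuration whose carriers
and durations lie entirely inside the detector's windows, so the configured
rate is the detectable rate and the comparison is meaningful.

## Statistics

The comparison scheme is normality-gated: Shapiro–Wilk at α = 0.05 on the
paired differences (within) or on each group (between); the gating
procedure itself is a package choice since the scheme being reproduced
names none. Parametric route: paired t / one-way ANOVA; nonparametric
route: Wilcoxon signed-rank / Mann–Whitney U (2 groups) / Kruskal–Wallis
with pairwise Mann–Whitney follow-ups when the omnibus is significant. All
tests two-sided at α = 0.05. Exact distributions are used for tie-free
samples up to n = 12 per group, normal approximation with continuity and
tie corrections otherwise; all-zero paired differences give p = 1 by
convention; degenerate (constant) samples are routed to the nonparametric
path, except all-constant between-group input which returns ANOVA F = 0,
p = 1. A forced `test =` override exists for both choosers, used by the
enumeration-oracle tests to pin the nonparametric path regardless of what
the gate would decide on a tiny sample. No multiple-testing correction is
applied, matching the emulated analysis; reports state this.

Summaries are mean ± SEM with the sample (n − 1) SD; SEM is refused for
n < 2.

## Pipeline and problem sizes

`run_study()` composes the stages over the default design (sham 7,
neuropathic 9, treated 8 animals; three 150-min sessions each; behaviour on
days 3 and 6), training one exemplar set per study from generator-drawn
constant-state segments — the in-silico analogue of picking typical
stretches by eye. Every animal-session yields one hypnogram, one event
list and one summary row; the comparison plan covers REM%, NREM%, spindle
density and mean frequency (within-group session pairs and between-group
per session) plus withdrawals and EPM closed-arm percentage. Identical
seeds give byte-identical results (tested).

The full-scale profile (150 min at 3000 Hz) reproduces the acquisition
geometry; `quick = TRUE` (15 min at 250 Hz) is the desk-scale profile used
for exploration. The test and acceptance suites run at 250 Hz with 2–60 min
sessions: 250 Hz is ample for analysis content below 40 Hz, and the chosen
session lengths give each stochastic check enough events for a stable
estimate (e.g. the 60-min recovery recording carries on the order of twenty
detectable spindles). The 3000-Hz default is exercised directly by the
length-arithmetic and I/O tests.

## Known limitations

- The generator's states are spectrally stationary within a state; real
  transitions are gradual and staging accuracy near bout boundaries is
  untested by construction.
- Duration refinement assumes a roughly raised-cosine burst envelope;
  strongly asymmetric spindles would bias durations low.
- The EPM renewal process always routes through the center zone; direct
  open-to-closed crossings do not occur in simulated tables (the scorer
  handles them fine).
- Behavioural and electrophysiological group-effect magnitudes are
  qualitative stand-ins; only directions are meaningful.
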