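---
title: "Methods: time-locking and synchronisation of dual-device physiological recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-locking and synchronisation of dual-device physiological recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multisync)
```

## The model

Two devices record the same physiological source. The research recorder
(EEG and ECG at 2000 Hz) is treated as the time reference; the vital-signs
monitor (ECG 250 Hz, impedance pneumograph 62.5 Hz, photoplethysmograph
125 Hz, 1 Hz numerics) runs on its own clock, modelled as an affine
transform of true time,

$$ t_\mathrm{dev} = \delta + (1 + \epsilon)\,t, $$

with offset $\delta$ (seconds) and drift $\epsilon$ (s/s, default 0 — drift
over the minutes-long sessions this package targets is far below the
marking latency, so it is modelled but not estimated). When a stimulus
trigger fires at true time $t$, each device stamps an event mark at
$t_\mathrm{dev} + L$, where the marking latency $L$ is drawn from a normal
distribution truncated below at a floor (latencies cannot be negative: the
mark can only trail the trigger's minimum transit time). Defaults are the
measured behaviour of the two paths: mean 0.5 ms, sd 0 for the direct
trigger path into the research recorder; mean 105 ms, sd 19 ms, floor 0 for
the network annotation path into the monitor. Only mean/sd/range of the
monitor path are empirically known, which is why a truncated normal — the
least-structured two-parameter choice with a hard floor — is used.

The package answers two questions about such a set-up and then exploits the
answer: *how precise is the marking* (marking-precision analysis), *how far
apart are the devices* (lag analysis), and, given both, how to extract
stimulus-locked evoked and vital-sign responses.

## The simulator and what it does (not) emulate

`simulate_session()` generates both devices' channels from shared analytic
source waveforms — a function of true time that each device samples on its
own clock grid. This makes sub-sample clock offsets exact by construction
(an offset of 334 ms is not an integer number of 250 Hz samples), which a
pipeline that resampled a stored 2000 Hz array could only approximate.
Monitor channels additionally pass a 0.5–40 Hz zero-phase band-pass
standing in for the monitor's inbuilt filtering, which on real hardware
cannot be switched off and is not documented; this approximation is good
enough for lag estimation, which only needs the QRS complexes to survive.

The sources are deliberately simple:

- **ECG**: a sum of Gaussian bumps per beat (dominant R wave, smaller P and
  T). Beat-to-beat variability is multiplicative log-normal on the RR
  interval (`hrv_sd`, default 0.03). Defaults are neonatal: 150 bpm.
- **Respiration**: one raised-cosine excursion per breath (width 0.9 s),
  scheduled every 1.5 s by default (40 breaths/min, neonatal).
- **Push-button artifact**: a negative deflection with a 20 ms linear
  attack to −depth and half-cosine recovery over 0.5 s. The attack is fast
  so the onset is sharp at 62.5 Hz, as the real artifact is.
- **Evoked EEG**: a packaged damped biphasic template (unit peak, support
  0–0.7 s) inserted at each stimulus with optional jitter and scaling in
  Gaussian noise. The template is synthetic: the genuine noxious-response
  template's coefficients are not distributed with this package, and any
  user-supplied waveform is accepted in its place.

None of this is clinically realistic morphology, and that is intentional:
every algorithm here depends on timing, amplitude ratios and band
occupancy, not on waveform shape. Consequently, passing tests demonstrate
that the *algorithms* recover known ground truth under controlled noise;
they do not demonstrate robustness to movement artifact, electrode pops,
apnoea-with-gasping patterns, or non-stationary drift found in real infant
recordings. Ground truth (beat, breath, stimulus and press times, the drawn
latencies, the clock offset) is returned in `$truth`, so every analysis can
be scored without re-simulation.

## Marking precision

Following the push-button procedure — pressing the button onto the shared
ECG electrodes during a background-noise recording leaves both an event
mark and a visible artifact on the pneumograph — `detect_artifact_onset()`
epochs the pneumograph from 1 s before to 1 s after the mark,
baseline-corrects to the pre-mark mean, sets a threshold at 3% of the
minimum value in the second after the mark, and returns the time of the
earliest sample in the epoch below that threshold. Two conventions are
deliberate:

- the scan covers the *whole* epoch, not just the post-mark second: the
  physical artifact precedes its delayed mark, so the onset is usually at
  negative times. The post-mark window only *defines* the threshold.
- latency is reported as `mark − onset`, positive when the mark trails the
  press.

Onsets are reported at sample resolution (the earliest below-threshold
sample), so latencies are quantised to the 16 ms pneumograph sampling
interval and detection is systematically up to one sample late; the
recovery tests budget two samples for this. Per-event manual overrides are
supported (`marking_precision(..., overrides = )`) for the occasional trace
where the automatic threshold mis-places a noisy onset. `precision_stats()`
reports mean, sd (n−1), min, max and per-session means.

## Inter-device lag

`estimate_event_lag()` epochs both ECG records 5 s either side of an event
time on their own time axes and returns the shift in ±`max_lag` maximising
their cross-correlation. Choices:

- both records are first brought to a common 12–40 Hz band at 250 Hz
  (`preprocess_monitor_ecg()`, `preprocess_research_ecg()`): the band kills
  slow movement drift, keeps QRS energy and makes the differently-filtered
  records comparable; the research record is also 50 Hz-notched and
  decimated 2000→250 Hz (zero-phase anti-alias low-pass, then every 8th
  sample, so no group delay is introduced).
- cross-correlation is computed on mean-removed epochs without amplitude
  normalisation; the argmax is invariant to global scaling.
- `max_lag` defaults to 2.5 s: well above plausible inter-device offsets
  (hundreds of ms) but below the epoch half-length, limiting the chance of
  locking onto a neighbouring heartbeat.
- ties break toward the smallest absolute lag (then the negative one), a
  rule that matters on near-periodic stretches and makes the estimator
  deterministic.

`session_sync_offset()` reports both the signed mean lag and the mean
absolute lag across a session's events, because both conventions are in
use and they answer slightly different questions once lags change sign.

## Evoked responses

`epoch_signal()` cuts inclusive `[-pre, +post]` windows (both endpoints
kept: `round(pre·rate) + round(post·rate) + 1` samples) and subtracts the
per-trial mean over the baseline interval, taken half-open `[from, 0)` so
the stimulus sample itself never leaks into its own baseline. EEG defaults
are −0.5…+1 s with a 0.5–30 Hz band-pass and 50 Hz notch; 1 Hz vitals use
−15…+45 s raw values for a single heel lance and −5…+10 s
baseline-corrected for stimulus trains.

`woody_align()` is a single-pass Woody alignment against a fixed template:
the shift within ±100 ms maximising the Pearson correlation, ties toward
zero, followed by a scalar least-squares fit of the shifted template — the
simplest reading of projecting a canonical waveform onto a response that
yields a magnitude. No iterative re-averaging is needed because the
template is fixed rather than estimated from the trials; the magnitude is
left unconstrained in sign. True latencies beyond the bound clamp to
±100 ms, which is the desired behaviour for a bounded latency correction.

## Respiration

`remove_cardiac_interference()` estimates the cardiac frequency from ECG
R peaks and low-passes the pneumograph below it (cutoff 0.6 × cardiac
frequency, floored at 0.7 Hz so 40 breaths/min breathing is never
attenuated); with no usable ECG it falls back to a fixed 1.5 Hz cutoff with
a warning. The zero-phase order-4 filter gives ≥ 20 dB attenuation at the
cardiac line one octave above the cutoff.

`detect_breaths()` is a documented adaptive-threshold detector (the
published infant detector it stands in for is not openly specified): it
walks the record excursion by excursion, keeps a running median of the last
5 accepted peak-to-trough amplitudes (initialised from the first 15 s
range), accepts an excursion as a breath when it exceeds 25% of that
statistic (refractory 0.3 s), and marks the breath at the linearly
interpolated rising crossing of 50% of the excursion amplitude. The
acceptance gate is deliberately lower than the timing fraction: it lets the
running statistic keep tracking through sudden amplitude changes (an exact
halving is detected with zero misses), while the timing crossing stays at
the conventional half-amplitude point. All constants are exposed.

`windowed_rr()` computes 60 / mean(IBI) in 20 s windows stepped by 1 s.
If the first or last breath in a window is more than 1.5 s from the window
edge, that gap is included as an additional interval, so a breathing pause
straddling the edge pulls the rate down instead of being ignored. One
subtlety: this padding lowers the rate exactly when the padded gap is
longer than the window's mean inside interval — the pause scenario the rule
exists for; for breathing slower than the gap it can raise the rate, which
is the correct behaviour of the stated rule, not a bug. Windows with no
breaths (or no usable interval) are flagged `defined = FALSE` rather than
given a fabricated rate.

## Numerical choices

- All filtering is zero-phase (forward–backward Butterworth) so no
  operation ever shifts event timing; inputs are odd-reflection padded
  before `filtfilt` to suppress edge transients.
- High-passes are implemented as baseline subtraction (the signal minus its
  low-passed trend). At 2000 Hz a direct 0.5 Hz Butterworth high-pass has
  poles too close to the unit circle for reliable forward–backward
  filtering; subtracting the low-passed trend is numerically robust and
  equally zero-phase. Band-passes are this high-pass followed by a low-pass
  (ECG band 12–40 Hz uses order 4/4; EEG 0.5–30 Hz order 2/4).
- Sample timestamp convention: sample *i* (0-based) of a record starting at
  `start` lies at `start + i/rate`; epochs anchor sample 0 at the grid
  point nearest the event. Event times are written to disk with 6 decimal
  digits so millisecond semantics survive CSV round trips.
- Degenerate inputs: zero-depth artifacts are identities; flat pneumographs
  yield empty breath sequences (apnoea is not an error); a post-mark window
  with no negative deflection raises a classed no-artifact error; events
  whose epoch does not fit the record are skipped with a warning (or raise
  an error in strict mode).

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
the scale the analyses were designed for: 7 sessions × 5 presses for
marking precision (35 events, matching the deposited-data design), 24 s
dual-ECG sessions across clock offsets 0–334 ms for lag recovery, all 401
integer shifts within ±100 ms at 2000 Hz for Woody alignment, and 60–80 s
breathing records for the respiration chain. The deposited push-button
recordings themselves are not redistributable; the test that reproduces
their published statistics reports their absence unless the user supplies
them under `inst/extdata/s1_data`.

## Known limitations

- Clock drift is modelled but never estimated; sessions are assumed short
  enough that a constant offset suffices.
- The monitor's inbuilt filter is an undocumented approximation.
- The breath detector is a documented stand-in, not a clone of the
  published infant algorithm, and its constants may need retuning on real
  pneumographs.
- The synthetic evoked template supports the machinery but carries no
  clinical meaning; magnitudes from it are not comparable to published
  noxious-response magnitudes.
- Real-world artifact classes (movement, electrode pop) are out of the
  simulator's scope, so detector robustness to them is untested here.
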