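---
title: "Methods: afterdischarge detection and BOLD baseline decline analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: afterdischarge detection and BOLD baseline decline analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nadbold)
```

## The problem this package addresses

A short train of 20 Hz pulses delivered to the rat perforant pathway
triggers *neuronal afterdischarges* (nAD) in the hippocampus: self-sustained
epileptiform spiking that outlasts the stimulation by roughly ten to twenty
seconds. The afterdischarge is followed by a *sustained decline of the BOLD
baseline* in the dorsal hippocampus that can last from tens of minutes to
beyond the end of a two-hour scan — a hemodynamic signature of the postictal
state. Quantifying this pair of phenomena requires two very different
measurement chains that this package implements side by side:

1. **Electrophysiology inside the scanner.** Dentate-gyrus LFP sampled at
   5000 Hz, contaminated by MR gradient bursts every TR (2 s) and by
   stimulation artifacts during the train. The scientific quantities are the
   afterdischarge *duration* and its *intensity* (rectified area under the
   curve per second).
2. **BOLD VOI time series.** One value per volume (TR 2 s, 3660 volumes,
   122 min), normalized to a grand mean of 100%, compared across conditions
   point by point, and scored for *recovery* of the post-stimulus decline.

Because the underlying animal recordings are not publicly deposited, the
package ships a seeded synthetic-data generator that emulates both chains
with known ground truth; every analysis stage is tested against that truth.

## LFP conditioning

Raw traces are processed in a fixed order: **blank, decimate, band-pass**.

* **Blanking.** Samples within ±5 ms of each stimulation pulse and ±10 ms of
  each volume trigger are replaced by linear interpolation between the window
  edges. Overlapping windows are merged first, which makes the operation
  idempotent and guarantees no sample is interpolated twice. Blanking comes
  *before* filtering because the large gradient/stimulus transients would
  otherwise ring through the 100 Hz low-pass and inflate the envelope for
  tens of milliseconds around every artifact. (Relying on the low-pass alone
  is supported via `condition_lfp(blank = FALSE)` for sensitivity analyses.)
* **Decimation 5000 → 1000 Hz.** An 8th-order zero-phase Butterworth
  anti-alias filter (cutoff 0.8 × the new Nyquist) precedes taking every 5th
  sample. Event times are carried over unchanged.
* **Band-pass 0.5–100 Hz.** Two 4th-order Butterworth sections (high-pass
  then low-pass), each applied forward–backward (`filtfilt`), so the chain is
  zero-phase: afterdischarge end times and population-spike latencies are not
  biased by filter delay. The trace mean is removed first and the signal is
  extended antisymmetrically about its endpoints before filtering; without
  that padding the ~2 s time constant of the 0.5 Hz high-pass leaves visible
  edge transients. Traces shorter than three high-pass time constants (6 s)
  are rejected rather than filtered unreliably.

The *baseline amplitude* — the detector's reference — is the mean absolute
value of the conditioned trace over the 60 s immediately preceding
stimulation, with blanked spans excluded. The mean absolute value (rather
than RMS) is used because the detection rule is phrased in terms of
amplitudes, not power; the window length is configurable
(`conditioning_config(baseline_window = )`).

## Afterdischarge detection and intensity

The end of the afterdischarge is defined as the first time after the train
at which elevated activity falls below **five times the baseline amplitude
for more than one second**. The implementation computes a rectified-envelope
estimate — a centered moving mean of `|x|` over 100 ms — and finds the first
time `t ≥ stim_end` such that the envelope stays below
`threshold_factor × baseline` throughout `[t, t + persistence]`. The 100 ms
window is a compromise: long enough to bridge the gaps between individual
spikes (~25 ms at typical afterdischarge rates), short enough that the 1 s
persistence rule is still resolved sharply. Brief sub-threshold dips shorter
than the persistence window do not terminate the event. If no qualifying
time exists within `max_search` (default 120 s) the event is **censored** at
that horizon and flagged, rather than failing.

Intensity is the integral of the rectified conditioned signal per
one-second bin from the stimulation end to the detected event end
(trapezoidal rule). A final partial bin is included pro-rata, so the summed
per-second values equal the integral over the whole event. The integral is
computed on the rectified signal rather than on the smoothed envelope; with
a different convention the values change by a scale factor common to all
groups, which cancels from every between-group comparison.

Two detector properties are enforced by tests: output equals a brute-force
sample-by-sample scan oracle exactly, and raising the threshold factor can
never lengthen the detected event.

## Population spikes

Test-pulse sweeps recorded before and after the scan are scored in a search
window 2–10 ms after the pulse (skipping the stimulus artifact): the peak is
the first sample attaining the window maximum, the trough the most negative
sample after it, amplitude the peak-to-trough difference. The latency
landmark is genuinely ambiguous in the field's shorthand ("from the stimulus
onset"); the package reports both times and uses the **trough** — the
conventional population-spike minimum — as the primary latency, switchable
to the peak via `latency_landmark`.

## BOLD analysis

* **Normalization** divides each series by its own grand mean (×100), making
  every series mean exactly 100% — deliberately *without* any detrending or
  high-pass: slow drifts of the baseline are the signal here, and a baseline
  correction would remove them.
* **Group time courses** are per-volume arithmetic means ± sample SD.
* **Pointwise testing** runs a two-sample equal-variance t-test at every
  volume with Bonferroni correction (`alpha = 0.01`, `m` = number of volumes
  tested, 3660 by default). The two-sample pooled form is the package
  default; a paired variant is provided because both conventions circulate
  for this design, and the choice is surfaced rather than hidden. Volumes
  with zero pooled variance get p = 1 by convention and are counted in the
  result.
* **Recovery** of the post-stimulus decline is declared at the first volume
  after stimulation from which the group mean stays at or above 98% of the
  pre-stimulation baseline (mean of volumes 900–959, i.e. minutes 30–32) for
  60 consecutive volumes (2 min). The persistence dwell is not part of the
  verbal criterion, which marks a recovered *period*; without it a single
  noise excursion across the 98% line would count as recovery. With it, on
  noisy group means the detected time is systematically later than the
  underlying crossing (the mean must clear the threshold by ~2 SD of its
  noise before a 2-min dwell survives); on noiseless traces the criterion is
  exact, which is how the closure tests are built. Series that never satisfy
  the rule are censored at the end of the recording (90 min post-stimulus),
  not treated as errors.
* **Condition subtraction** isolates stimulus-locked effects: the matching
  unstimulated control group mean is subtracted volume by volume and the
  difference re-anchored at 100%. SDs are propagated in quadrature, treating
  the two groups as independent (the groups contain different animals; the
  appropriate SD treatment for difference traces is not standardized, and
  quadrature is the conservative independent-groups choice).

Volume indices are 0-based throughout (`values[stim_volume + 1]` in R),
so that volume *k* spans `[k·TR, (k+1)·TR)` and "image 900 to 959" is
exactly minutes 30–32.

## Inference toolkit

All group tests work from raw vectors *or* printed summaries
(`summary_stats(mean, sd, n)`), and the two paths agree to machine precision
when the summaries are exact — this is what allows published mean ± SD
tables to be re-analyzed directly.

* Two-sample tests pool the variance (df = n₁+n₂−2); Welch is available but
  never the default.
* **TOST equivalence** is realized through the confidence-interval inclusion
  rule: two one-sided tests at α = 0.05 succeed exactly when the two-sided
  90% CI of the difference lies strictly inside the margins; that CI is also
  the reported quantity.
* The **sample-size rule** n = 16/Δ², Δ = δ/σ, is the standard rule of thumb
  for ~80% power at two-sided α = 0.05; with the design values δ = 0.5% and
  σ = 0.2% it gives Δ = 2.5 and n = 2.56, hence ≥ 5 animals per group is
  comfortable.

One reproducibility note: re-deriving the published 90% CIs from printed
summaries works to ±0.02 for the isoflurane duration and medetomidine
intensity comparisons; the medetomidine *duration* CI does not reproduce
from its printed mean/SD values under any standard pooled computation
(plausibly a rounding or transcription artifact in the source table), so it
is not used as a check anywhere in the package.

## The synthetic-data generator

The generator's defaults are the study conditions: 5000 Hz LFP, gradient
artifacts every 2 s, a 160-pulse 20 Hz train at 32 min, afterdischarge
duration regimes of 13.01 ± 4.42 s (isoflurane), 11.64 ± 1.80 s
(isoflurane + acetaminophen), 13.25 ± 1.85 s (medetomidine) and
13.66 ± 1.87 s (medetomidine + acetaminophen); BOLD noise SD 0.2%,
drift regimes per anesthetic (isoflurane rising to ~+1.6% in the first hour
and settling at +1.39%; medetomidine flat for 30 min then declining to
−4.93%; acetaminophen delaying the isoflurane rise and advancing the
medetomidine decline), a transient positive response and spontaneous BOLD
waves under medetomidine only, and stimulus-locked declines of 3% whose
recovery times are condition defaults (censored under isoflurane, 70 min
with acetaminophen, 41 min under medetomidine, censored with
medetomidine + acetaminophen). All shapes are the simplest forms consistent
with the verbal descriptions — saturating or piecewise-linear drifts, a
step decline with linear return — and are calibration targets, not
physiological claims.

Two generator decisions deserve explanation:

* **The afterdischarge waveform is quasi-rhythmic, not Poisson.** The burst
  is a ~40 Hz spike train with gamma-distributed inter-spike intervals
  (shape 20, i.e. low jitter) convolved with a biphasic
  derivative-of-Gaussian kernel (σ = 4 ms, spectral peak near 40 Hz), mixed
  with an elevated Gaussian floor. A homogeneous Poisson train at the same
  rate leaves ~50% relative fluctuation in a 100 ms envelope window, which
  makes the event's own end time statistically ill-defined at the ±0.2 s
  level the closure tests work to; rhythmicity is also the more faithful
  description of afterdischarge spiking. The kernel bandwidth matters for a
  subtler reason: a very sharp (4 ms wide, ~250 Hz) kernel would be almost
  entirely removed by the 100 Hz conditioning low-pass, so the generated and
  conditioned envelopes would disagree.
* **Amplitudes are calibrated in the conditioned domain.** Component scales
  are set by passing each component through an emulation of the standard
  conditioning chain and measuring the resulting envelope, so that "the
  plateau sits at 10× baseline" is true where the detector operates. The
  envelope decays linearly over the final 20% of the event and is laid out
  so it crosses the 5× threshold exactly at `nad_duration` — the generated
  duration *is* the crossing time, which is what makes truth-recovery
  closure a well-posed test. The background's contribution to the rectified
  envelope is accounted for with the independent-Gaussian quadrature
  correction `sqrt(env² − 1)`.

What the generator does **not** emulate: pink/physiological background
spectra, respiration and cardiac modulation of the LFP, scanner drifts that
are non-smooth in time, spatial structure of the VOI (beyond the optional
phantom used to test mask extraction), motion, and any hemodynamic
convolution linking the two modalities. Passing closure tests therefore
demonstrates the correctness of the *analysis* under the stated generative
assumptions, not robustness to every property of real data.

## Numerical choices and degenerate inputs

* Zero-phase filtering throughout; filter warm-up enforced (3 time
  constants); a processed-flag prevents accidental double filtering.
* The detector errors on a zero baseline amplitude (threshold undefined);
  zero-duration events yield zero bins and zero total intensity.
* `first_sustained` (shared by the detector and the recovery criterion)
  counts a run that starts before the search point from the search point
  onwards, so activity already quiet at stimulation end gives duration 0.
  Recovery searches volumes strictly after the stimulation volume, so the
  minimum recovery time is one volume (TR), not 0.
* Pointwise tests with zero pooled variance return p = 1 and are counted.
* Means of masked voxels are computed in double precision regardless of the
  on-disk dtype; the text containers write doubles with 17 significant
  digits so write→read round-trips are bit-exact.

## Problem sizes used in the shipped tests

The test suite and acceptance script generate everything at run time. LFP
closure uses 20 sessions with true durations spread over 3–25 s (windows of
~80–105 s around the train rather than full 122-min sessions); recovery
closure uses full-length 3660-volume series; the end-to-end determinism
check runs the full eight-group design with five animals per group twice
and compares output files byte for byte. These sizes keep the whole suite
at a few minutes on one core while leaving every scientific parameter at
its study value.

## Known limitations

* The HDF5 mirror of the LFP container is not provided in this build; the
  delimited-text container is the native format.
* Recovery on noisy group means is conservative (late) by construction of
  the persistence dwell; a per-animal recovery mode exists for sensitivity
  analysis but group-mean recovery is the primary output.
* The intensity measure is reported in mV·s ("arbitrary units" across
  electrode placements); absolute values are comparable only within an
  electrode/session.
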