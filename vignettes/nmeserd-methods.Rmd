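---
title: "Methods: artifact removal and ERD quantification for EEG under NMES"
author: "nmeserd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: artifact removal and ERD quantification for EEG under NMES}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nmeserd)
```

## The problem

Neuromuscular electrical stimulation (NMES) excites motor and sensory
nerves through the skin; the afferent volleys it generates modulate
sensorimotor cortical oscillations, visible in EEG as event-related
desynchronization (ERD) of the rolandic alpha (7–13 Hz) and beta
(14–30 Hz) rhythms. Measuring this is hard for two reasons. First, every
stimulation pulse couples capacitively into the recording and appears as a
high-amplitude transient of roughly 5 ms in every channel. Second,
electrodes whose skin contact has degraded behave like antennas and are
disproportionately contaminated — both by the stimulation and by 50 Hz
power-line noise, which makes the latter a usable *detector* for the
former. `nmeserd` implements the full chain from raw (or simulated)
recordings to intensity and dose-effect summaries, in this order:

1. block-wise rejection of bad-impedance channels (48–52 Hz power),
2. sliding median filtering of the stimulation transients,
3. common average reference (CAR), 0.1–45 Hz band-pass, epoching to
   (−4, +4) s around stimulation onset, downsampling to 100 Hz, pooling
   by intensity,
4. Morlet wavelet time–frequency ERD/ERS maps and scalar summaries,
5. trial-wise linear dose-effect regressions.

## The synthetic session generator

Real recordings of this kind are not publicly distributable, so the
package ships a generator whose output has *known* ground truth; every
downstream stage is tested against it. A session consists of 9 blocks of
18 trials (3 blocks per intensity, randomly ordered); each trial is a
ready cue, a stimulation interval of uniform random length 3.4–3.8 s
beginning 2.6–3.0 s after the cue, and a 3 s inter-trial pause.
Inter-block breaks default to 150 s but are compressible — downstream
stages use annotation timing, not file length, so tests shrink them to
keep simulated recordings small.

Each EEG channel contains:

- **1/f background**: Gaussian noise spectrally shaped to
  PSD ∝ 1/f (flat below 0.5 Hz), RMS 10 µV. This emulates broadband
  cortical background activity.
- **Rolandic oscillators** at the contralateral sensorimotor ROI
  (C3, C1, CP3, CP1): narrowband Gaussian noise filling 7–13 Hz
  (RMS 10 µV) and 14–30 Hz (RMS 6 µV), i.e. a strong mu rhythm. Occipital
  alpha (8 µV, unmodulated) is added at O1/O2 for realism.
- **Planted ERD**: during each stimulation interval the oscillator
  envelope is scaled by `sqrt(1 + erd/100)` with 200 ms raised-cosine
  transitions, so the *power* change matches the percent-change
  definition used by the analysis. Because the planted `roi_erd` is
  defined on the total channel signal while the envelope only modulates
  the oscillator, the generator analytically compensates the modulation
  depth for the unmodulated in-band 1/f floor (a factor of ~1.08 for
  alpha at the default amplitudes). Optional per-trial drifts implement
  session-wide habituation (`habituation_slope`, percent per pooled
  trial) and within-block attenuation that resets at each block boundary
  (`within_block_slope`).
- **Artifacts**: a 35 Hz train of biphasic 5 ms transients during each
  stimulation interval, with per-intensity peak amplitude (defaults
  200/400/800 µV) and a fixed random per-channel gain in 0.5–1.5 so that
  the artifact is *not* spatially uniform (a spatially uniform artifact
  would be removed by CAR alone, hiding the median filter's
  contribution). A 50 Hz sinusoid of 1 µV models baseline power-line
  pickup; designated bad channels receive 20 µV.
- **Muscle channels** carry a 5× amplified copy of the artifact train
  plus 2 µV sensor noise; onset alignment uses them.

One master seed fans out to independent substreams (timeline, background,
oscillators, artifact gains, power line), so disabling one component does
not change the realization of the others — essential for
artifact-on/artifact-off contrasts.

What the generator does **not** emulate: volume conduction and realistic
scalp topography (sources are channel-local), evoked potentials at
stimulation onset, amplitude non-stationarity of real mu rhythms, muscle
fatigue, or impedance drift (off by default, deliberately). Passing tests
therefore show that the *pipeline* recovers what was planted under
realistic noise and artifact conditions; they are not evidence about any
particular real dataset.

## Channel rejection

Per block, a working copy of the EEG is high-pass filtered at 0.1 Hz
(4th-order Butterworth, zero-phase) and each channel's mean 48–52 Hz power
is estimated with Welch's method (1 s Hamming windows, 50% overlap) over
the block's 8 s trial windows. Channels above `mean + 4 SD` are discarded,
the statistics are recomputed on the survivors, and the loop runs to a
fixed point. Numerical conventions:

- **SD = 0** (e.g. identical channels): nothing exceeds the threshold;
  rejecting at `mean + 0` would spuriously discard half the montage.
- **Fewer than 4 survivors** abort with a diagnostic — the mean/SD
  statistic is meaningless on so few channels. Note that a
  `mean + 4 SD` rule *cannot* flag anything for n ≤ 17 channels (the
  largest achievable z-score in a sample of n is `(n−1)/√n`); the rule is
  built for full montages.
- Rejection is per block; a channel rejected in one block is excluded
  from ROI averages for that block only (per-trial channel masks),
  maximizing retained data.
- The returned data are the original (unfiltered) samples of the retained
  channels; the high-passed copy exists only for spectral estimation.

## The sliding median filter

A 10 ms window slides in steps of one sample; each output sample is the
median of the window centred on it. At 1000 Hz the window is 10 samples
(even), and the median is the mean of the two middle order statistics;
the centre is taken as `floor(w/2)`, so the filter has no group delay and
ERD latencies stay aligned to stimulation onset. The default edge policy
shrinks the window at the signal ends (no fabricated data); reflection is
available as an alternative. The implementation is a small C++ kernel,
checked exactly against a brute-force per-window sort in the tests.

Why 10 ms: it fully covers the ~5 ms transient, so the window's order
statistics are dominated by clean samples. This requires the transient to
be *biphasic* — with at most two or three strong same-sign samples, the
contaminated samples land at the extremes of the sorted window and never
reach the middle. The generator's default transient shape,
`c(1, 0.7, -0.9, -0.6, 0.05)` at 1 kHz, was chosen on exactly that
criterion: with it, a unit-amplitude 35 Hz transient train riding on a
10 Hz sinusoid retains under 5% of its 35 Hz power after filtering while
the carrier loses under 2% of its amplitude.

The filter's frequency response is characterised by
`attenuation_profile()`: a long unit sinusoid per frequency is filtered
and the surviving **peak** amplitude measured over an integer number of
cycles away from the edges. The profile rises from ~0% at low frequencies
to complete attenuation at 100 Hz (the frequency whose period equals the
window), passing 1.28%, 4.89% and 10.94% at 10, 20 and 30 Hz. The peak
measure is the right one here: the median filter flattens sinusoid
extrema, which is where its distortion concentrates; a Fourier-coefficient
measure of the fundamental reports 4–6× smaller numbers and understates
the distortion.

## Preprocessing conventions

- **CAR before band-pass**, computed per block over that block's retained
  channels only — contaminated channels would re-inject artifact through
  the mean.
- **Band-pass 0.1–45 Hz, 1st-order Butterworth, zero-phase**
  (forward–backward, effective order doubled). Zero-phase application
  preserves response latency; the price is the squared magnitude
  response, whose gain at 10 Hz is ~0.96. A first-order filter with a
  45 Hz cutoff necessarily attenuates 10 Hz by a few percent; this
  cancels exactly in the ERD ratio and is therefore accepted rather than
  compensated.
- **Onset alignment** uses the rectified muscle signal thresholded at
  `median + 8 MAD` (MAD, not SD, because the artifact's own heavy tail
  would inflate an SD-based threshold), searching ±0.5 s around each
  annotated onset; events without a crossing fall back to the annotation.
- **Epochs** span `[−4, +4)` s, left-closed — exactly `8 × fs` samples,
  an unambiguous integer count (800 samples at 100 Hz).
- **Downsampling** to 100 Hz is plain decimation by 10; the 45 Hz
  band-pass already provides the anti-alias protection.
- Pooling concatenates trials of one intensity across blocks in
  acquisition order, which the dose-effect regression requires.

## ERD/ERS quantification

Time–frequency power is computed with complex Morlet wavelets, 1–45 Hz in
0.5 Hz steps, 7 cycles wide (configurable; 7 is common sensorimotor-rhythm
practice). Wavelets are unit-energy normalised, so white noise yields flat
expected power across frequencies; any per-frequency scale cancels in the
percent-change normalization

\[ \mathrm{ERD/ERS}_j = \frac{P_j - \overline{P}_{\mathrm{baseline}}}{\overline{P}_{\mathrm{baseline}}} \times 100, \]

with the baseline taken at (−2.5, −1.5) s. Condition maps are
**average-then-normalize**: trial-averaged power enters the formula, so
the baseline-interval mean of a condition map is identically zero.
Single-trial series (dose-effect) instead normalize each trial's
stimulation-interval power by the intensity's grand-average baseline, so
all trials of an intensity share one reference. Scalar summaries average
the percent map over a band's frequency bins, then over an interval —
stimulation (0.5, 2.5) s, chosen to start clear of the onset-evoked
response, or non-stimulation (−3, −1) s — then over the available ROI
channels (unweighted, mask-aware).

Edge handling: wavelets at frequency f are contaminated within
`n_cycles/(2f)` seconds of the epoch edges. The ±4 s epochs leave ≥ 1 s of
guard around every analysis interval, which is safe for ≥ 3.5 Hz at
7 cycles; below that (down to the 1 Hz analysis floor) `erd_percent()`
emits a warning naming the lowest safe frequency rather than silently
using contaminated samples.

## Dose-effect analysis

Per band and intensity, the single-trial ERD series (acquisition order,
1-based trial index, block gaps ignored) is fit by ordinary least squares
against trial index; Pearson's r and its two-sided p-value quantify the
trend, at α = 0.05 with no multiple-testing correction (the regressions
are reported individually, as raw p-values). A zero-variance series is
reported as r-undefined rather than NaN. Block-wise regressions use the
within-block trial index, and the between-block reset statistic — first
ERD of block k+1 minus last ERD of block k — operationalizes the
qualitative observation that each new block starts with a restored
(more negative) ERD; it is exported but not significance-tested.

## Problem sizes and tolerances in the tests

The test suite simulates compressed sessions (inter-block breaks of
8–10 s; 3 blocks × 18 trials for recovery checks, 9 × 18 for accounting)
— sizes at which ERD sampling error over 54 pooled trials is ~1–2
percentage points, comfortably inside the ±5 to ±8 point tolerances used.
Planted-versus-recovered checks: ROI alpha ERD of −40% is recovered to
within a few points through the full cleaned pipeline (the residual gap
comes from wavelet band-edge and temporal smoothing, which the generator
deliberately does not compensate); a planted habituation slope of
+0.5%/trial is recovered with <10% bias over 20 fixed seeds; the Pearson
test's type-I error on null series is verified at 5% over 1000
Monte-Carlo draws. The brute-force median oracle and the EDF+ round-trip
are exact (to the 16-bit quantization step, computed from each signal's
stored physical range).

## Known limitations

- EDF+ support covers the continuous, single-annotation-signal layout the
  package writes; it is not a general EDF reader.
- The generator's oscillators are channel-local; scalp-map realism
  (volume conduction, reference effects beyond CAR) is out of scope, as
  is rendering topographic maps.
- Across-subject statistics (repeated-measures MANOVA, post hoc tests)
  are deliberately not implemented; `run_pipeline()` exports per-condition
  tables that any statistics package can consume.
- Epoch sets are in-memory R objects; persist them with `saveRDS()` if
  needed.
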