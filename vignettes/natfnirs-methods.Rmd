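---
title: "Isolating sustained-attention hemodynamics from naturalistic infant fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating sustained-attention hemodynamics from naturalistic infant fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In naturalistic (free-play) infant fNIRS there is no stimulus onset to epoch
against. This package implements a protocol that derives the "design matrix"
from the infant's own behavior: video-coded look bouts are segmented into
*sustained-attention events*, and the hemodynamic analysis contrasts the
sustained-attention phase of a look against its own first seconds — the
pre-attention/orienting phase — used as an *active baseline*. The heart-rate
literature on infant attention motivates the timing: sustained attention
begins roughly 5 s after a look starts, and stimulus-evoked HbO rises become
detectable 5–8 s after neural onset, peaking later still.

The pipeline has seven stages, each an exported module: synthetic-data
generation (`sim_config()`, `simulate_study()`), behavioral event extraction
(`merge_bouts()`, `extract_events()`, `participant_gate()`), signal
preprocessing (`preprocess()`), epoching (`extract_blocks()`,
`peak_window_mean()`), ROI/channel inference (`roi_stats()`,
`channelwise_stats()`), a cluster-mass sign-flip permutation test
(`cluster_permutation_test()`), and the onset-shift validation harness
(`run_validation()`).

## Behavioral segmentation

A look bout ends only when the infant looks away for more than 100 ms
(`merge_bouts()`, `gap_merge_ms = 100`); bouts strictly longer than 8 s
become sustained-attention events (`extract_events()`; the boundary case of
exactly 8 s is excluded because the rule is "more than 8 s"); event duration
is capped at 15 s to bound within-participant variability; and participants
contribute at least 5 events or are excluded (`participant_gate()`). Only
looks at toys are analysed by default — non-toy sustained looks are rare and
are filtered by configuration (`allowed_targets`), not hard-coded.

## Preprocessing

`preprocess()` mirrors a HOMER-style chain, deterministic end to end:

1. **Pruning** (`prune_channels()`): channels whose mean raw intensity at
   either wavelength falls outside (2, 10) device units are flagged;
   recordings shorter than 5 min or with more than half their channels
   flagged are rejected outright (a distinct, classed condition). The
   published bounds are quoted in concentration units, which cannot apply to
   raw intensities; we keep the numbers and read them as device-unit
   amplitude bounds, configurable. The source–detector distance filter
   (0–45 mm) passes all 20 mm channels.
2. **Optical density** (`intensity_to_od()`): $-\log_{10}(I/\bar I)$ per
   channel and wavelength.
3. **Wavelet motion correction** (`wavelet_correct()`): periodised
   orthogonal db2 transform, 4 levels; detail coefficients beyond
   0.8 × IQR outside the quartiles are zeroed. The transform is written
   in-package (tested for perfect reconstruction) because no wavelet
   library is among the package's dependencies; db2/4-level is the
   published convention of the wavelet-correction literature.
4. **Spline correction** (`spline_correct()`): motion segments are found by
   a 1-s moving-SD detector at 5 × the median SD (the toolbox the protocol
   delegates this to does not print its defaults; this is the conventional
   rule), then a smoothing spline with csaps-style parameter p = 0.99
   (mapped to `smooth.spline`'s `lambda = (1-p)/p`) is subtracted within
   each segment and the series re-anchored so persistent baseline steps are
   removed. Samples outside masked segments change only by level
   re-anchoring.
5. **Band-pass** (`bandpass()`): zero-phase 3rd-order Butterworth high-pass
   at 0.01 Hz and low-pass at 1 Hz (feasible at the 5 Hz sampling rate),
   applied forward-backward so epoch timing is never phase-shifted.
6. **Beer–Lambert inversion** (`mbll()`): per channel and sample the 2×2
   system in (ΔHbO, ΔHbR) is solved with DPF = (5.1, 5.1), 20 mm
   separation, and extinction coefficients interpolated from the packaged
   table at 763/841 nm. Concentrations are reported in µM.

## Epoching and the peak-window statistic

Each event contributes an 18-s block: a 3-s baseline beginning 3 s before
the *shifted* onset, and a 15-s post-stimulus window (90 samples at 5 Hz,
half-open convention, onset mapped to the nearest sample). The protocol
shift is +3 s into the look, so the baseline covers the
pre-attention/orienting phases. Events whose baseline would begin less than
5 s after the previous event's block end are excluded
(`exclude_short_isi()`), preventing the delayed response from bleeding into
the next baseline; blocks truncated by the recording edges are discarded
and counted. Baseline correction subtracts the per-channel baseline mean
and is idempotent.

Per participant and channel, blocks are averaged and a peak is located
inside the activation window (default: the whole 15-s post-stimulus block —
the protocol's "defined activation window" is not quantified, so it is a
configuration knob); the response is the block-average mean over ±2.5 s
around the peak, clipped at the block edges (clipping, rather than
discarding, keeps every participant estimable when the peak sits near 15 s).

**How the peak is defined matters.** Two modes are implemented
(`epoch_params(peak_mode=)`):

* `"abs"` (default): the sample with the largest *absolute* deflection; the
  response keeps its sign. Under a null (no event-locked signal) this
  statistic is symmetric around zero, so the downstream one-sample t-tests
  are calibrated and sign-flipping extracted responses is exactly
  equivalent to sign-flipping the underlying traces.
* `"directional"`: the maximum for HbO and the minimum for HbR. This reading
  of "peak" carries a selection bias of roughly one standard deviation of
  the block-average noise: under the null every channel's expected response
  is strictly positive, one-tailed t-tests become badly anti-conservative
  (simulated null ROI t-values of 3–6 at n = 12), and even an exact
  permutation test loses power because the bias inflates the null cluster
  masses. On real data, both modes coincide wherever a genuine response
  dominates (a positive HbO response peaks at its maximum; a negative HbR
  response at its minimum).

The default is `"abs"` because it is the only reading under which the
protocol's own published behavior is reproducible: near-zero t-values in
null regions and a randomized-onset control that abolishes significance.

## Inference

ROI values are the mean of a participant's surviving channel responses in
the ROI (participants with no surviving channel are dropped from that ROI
only, which is how per-ROI degrees of freedom become heterogeneous). HbO is
tested one-tailed for an increase, HbR for a decrease; `d = mean/sd`; post
hoc power uses the noncentral-t at α = 0.05. FDR control is
Benjamini–Hochberg by default: with six ROI p-values, the π₀-smoothing
q-value estimators are unstable, so the Storey mode is provided only with a
fixed, user-supplied π₀ (`fdr_adjust(method = "storey", pi0 =)`).

The spatial test (`cluster_permutation_test()`) thresholds channel t-values
at t > 2.0, groups spatially adjacent supra-threshold channels via the
channel adjacency graph, sums t-values into cluster masses, and compares the
observed masses with a max-mass null distribution built by flipping whole
participants' signs (the full channel vector flips together, preserving
spatial correlation). One-sided, positive masses only, matching the HbO
hypothesis. The test is exact under the sign-symmetry null: in `"trace"`
mode the peak-window statistic is recomputed inside every flip — cheap,
because the statistic of a negated trace is the negated around-opposite-
extremum statistic, and with the `"abs"` peak the two coincide. p-values use
the add-one convention `(1 + #{null ≥ obs})/(1 + n_perm)`, valid for any
permutation count; all 2ⁿ sign patterns are enumerated exhaustively
whenever 2ⁿ ≤ 4096 (so n ≤ 12 studies are exact by enumeration, not
sampling).

## The synthetic-data generator

`simulate_study()` generates what the analysis assumes real sessions look
like, with known ground truth:

* **Behavior**: alternating lognormal gaps (meanlog 1.3, sdlog 0.7; mean
  ≈ 4.7 s) and look bouts (meanlog 1.0, sdlog 0.9; mean ≈ 4.1 s,
  heavy-tailed so ~11% of bouts exceed 8 s), targets drawn toy-dominant.
  These defaults sit inside the published range of mean look durations
  (1.84–5.69 s across targets) and yield roughly 9 sustained toy events per
  20-min session, comfortably above the 5-event inclusion gate.
* **Hemodynamics**: every look longer than 8 s drives a boxcar starting 5 s
  into the look (the sustained-attention latency), convolved with a
  canonical double-gamma HRF (peak 5.5 s, undershoot 15 s, ratio 1/6 —
  the published timing is qualitative, so the canonical shape with a
  configurable peak delay is used). The response is added to three adjacent
  left-temporo-parietal channels (9–11); HbR is −1/3 of HbO, the simplest
  model consistent with opposing chromophore traces. Amplitude: 0.75 µM at
  the peak of a reference 10-s episode.
* **Optics**: latent concentrations are forward-projected to ΔOD at
  763/841 nm through the same extinction table, pathlength and DPF the
  inverse step uses, and exponentiated onto a baseline intensity of 5
  device units — mid-band of the (2, 10) pruning bounds, so the pruning
  rule stays exercisable (raw-unit scales are device-specific).
* **Noise and artifacts** (OD scale): random-walk drift (SD 0.010),
  Mayer-wave (0.002 at 0.1 Hz) and respiratory (0.001 at 0.4 Hz)
  oscillations with channel-random phase, white noise (0.004), and a
  per-participant lognormal scale factor (sdlog 0.3) emulating the large
  SNR heterogeneity of infant recordings. Motion artifacts are 0.3-s
  spikes (1/min, 0.03 OD) and baseline shifts (0.3/min, 0.015 OD) —
  a *post-QC* artifact load, because the emulated study analysed only
  participants who passed optode-coupling quality control.

The effect amplitude is the one deliberately "detectable" setting: the
design target is that the planted 3-channel cluster is recovered at
p < 0.05 in at least 80% of replicate studies at the protocol shift — a
desk-scale power check of the whole pipeline. A pilot calibration
(10 replicates per candidate) gave 10% recovery at 0.5 µM under a heavy
(pre-QC) artifact load, 70% at 0.5 µM post-QC, and 100% at 0.75 µM
post-QC; 0.75 µM — mid-range for infant fNIRS — was frozen as the default.

What the generator does *not* emulate: cardiac pulsation (unresolvable at
5 Hz), photon-migration optics, caregiver-speech or motor confounds
correlated with attention, and systemic physiology coupled to behavior. A
green test suite therefore shows the pipeline recovers what it assumes;
it cannot show that real free-play data satisfy those assumptions.

## Validation harness

`run_validation()` reruns epoching → statistics → cluster test on identical
preprocessed data under alternative onset definitions: the protocol (+3 s),
aligned (+0 s), postponed (+6 s), and randomized (per-event random sign,
magnitude uniform on 15–30 s; the whole 18-s window moves as one unit).
Because all conditions share one underlying signal, the +0 condition's peak
latency exceeds the +3 condition's by exactly the 3-s shift (within one
sample) wherever the delayed peak stays inside the 15-s window — channels
whose peak would land beyond it clip to the window edge, the "response
extends past the block" regime the +3 shift was designed to avoid. The
randomized condition is the negative control: at the study's corrected
significance level (FDR q < 0.05 for ROIs, cluster p < 0.05) it should
abolish findings in the overwhelming majority of replicates. Comparison
across conditions is deliberately descriptive (tables of deltas), as the
protocol's own validation was by inspection.

## Numerical choices and degenerate inputs

* Onsets map to the nearest sample; all windows are half-open `[start, end)`.
* Zero-variance responses make t undefined: a classed error, never silent.
* Channels with no usable block yield missing responses, never zeros.
* Recordings are rejected (vs channels pruned) through distinct error
  classes so pipelines can log attrition correctly.
* The wavelet stage warns and passes through on series shorter than the
  filter support; the spline stage falls back to linear re-anchoring on
  segments shorter than 8 samples.
* Filtering edge behavior is exactly `signal::filtfilt`'s (zero padding);
  the band-pass contract is verified on mid-series samples.
* Exhaustive sign-flip enumeration replaces sampling whenever 2ⁿ ≤ 4096.

## Test problem sizes

The acceptance suite replicates the study design (12 infants, 20-min
sessions, 44 channels) 50 times for the recovery and randomized-onset
checks (199 Monte-Carlo sign-flips per cluster test), uses 6 of those
replicates for the latency contrast, and runs 200 null replicates at a
reduced design (8 infants, 300-s sessions, artifacts disabled, motion
correction skipped accordingly) for the cluster-level false-positive
calibration; these sizes are the package's choice of a desk-scale
experiment. Randomized-onset "abolition" is judged on the ROI family at
the corrected level (q < 0.05), the same decision rule the protocol
reports; with two test families or uncorrected thresholds even a perfectly
calibrated procedure would show nominal-rate failures. `scripts/acceptance.R` reports the same quantities
from a single seed plus a 10-replicate sweep.

## Known limitations

* ROI membership and channel adjacency ship as illustrative configuration:
  the real array's geometry is cap-specific and must be supplied by users.
* The `"directional"` peak mode reproduces the protocol's wording literally
  but is statistically biased under the null; it is provided for
  sensitivity analyses, with the bias documented above.
* HbR is simulated as a scaled negative HbO copy, so HbR inference on
  synthetic data is not an independent check of chromophore physiology.
* No SNIRF reader/writer: recordings interchange via a documented
  long-format CSV (`write_recording_csv()`), annotations via tab-delimited
  text, ground truth via JSON.
* One session per participant; multi-session concatenation is out of scope.
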