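---
title: "Methods: carotid Doppler VTI, the Doppler Shock Index, and a simulated Valsalva cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carotid Doppler VTI, the Doppler Shock Index, and a simulated Valsalva cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early central blood-volume loss is hard to see in routine vital signs:
healthy people defend their blood pressure until a large fraction of volume
is gone. Blood *flow* indices react earlier. A wearable continuous-wave (CW)
Doppler patch over the common carotid artery measures beat-by-beat maximum
blood velocity; the area under the maximum-velocity envelope across one
cardiac cycle is the velocity time integral (VTI, in cm) — the distance a
column of blood travels per beat, proportional to flow for a fixed vessel
area. Dividing heart rate by carotid VTI gives the Doppler Shock Index
(DSI, bpm/cm), a flow-based analogue of the classic shock index
(heart rate / systolic blood pressure).

`dopplervti` implements the full measurement chain as a tested pipeline:

1. **Simulation** (`simulate_cohort()`, `make_velocity_track()`,
   `synthesize_audio()`): ground-truth hemodynamics and two-channel Doppler
   audio (carotid CW patch; pulsed-wave descending-aorta reference) for a
   standardized Valsalva maneuver.
2. **Envelope tracing** (`compute_spectrogram()`, `trace_max_frequency()`,
   `trace_envelope()`): short-time Fourier spectrogram plus an
   integrated-power-percentile maximum-frequency tracer, converted to
   velocity via the Doppler equation.
3. **Beat segmentation** (`detect_beats()`, `beat_table()`): cardiac-cycle
   onsets, per-beat VTI and heart rate.
4. **Protocol windowing** (`define_windows()`, `subject_windows()`): window
   means, DSI/SI, percent changes.
5. **Statistics** (`paired_t_test()`, `detection_metrics()`,
   `sweep_thresholds()`, `cohort_stats()`): paired two-tailed t-tests and
   sensitivity/specificity of detecting a 10% fall in the aortic reference
   VTI.

Because no subject-level recordings are publicly available, the simulator is
a first-class module: it encodes the published group-level physiology and
lets every downstream stage be validated against known truth.

## The Valsalva protocol and its analysis windows

A standardized Valsalva maneuver has four 15-s phases: resting baseline,
inspiratory hold (strain against 20–25 cm H2O), release hold, and recovery —
60 s in total. The analysis windows are half-open intervals:

* **T1** (baseline): seconds 5–10 of the baseline phase;
* **T2** (peak strain): the terminal 5 s of the inspiratory hold
  ([25, 30) for the default phases);
* **T3** (recovery): the terminal 5 s of the recovery phase ([55, 60)).

Beats belong to a window when their onset falls inside it; window values are
unweighted means over kept beats. Window-level DSI is the ratio of
window-mean heart rate to window-mean VTI (a per-beat-DSI average is
available via `per_beat_dsi = TRUE`); this matches how window quantities are
conventionally reported. The slow noninvasive monitor channel (stroke
volume, MAP, SBP every 20 s) uses its own convention: T1 is the sample
immediately before protocol onset, T2 the smallest during-protocol SV sample
(earliest tie), T3 the final sample.

## The virtual subject

A `valsalva_profile()` drives every tracked quantity by a smooth multiplier
trajectory: 1 during baseline, a monotone smoothstep ramp across the hold
reaching the `hold_*_multiplier` over the terminal 5-s plateau, then a ramp
to the `recovery_*_multiplier` with a matching terminal plateau. Because the
plateaus coincide with the analysis windows, the programmed multipliers are
exactly the window-mean effects when jitter is off — the calibration-closure
property the test suite asserts.

The calibrated `"responder"` preset encodes the group-mean effects of a
healthy-volunteer Valsalva cohort: carotid VTI ×0.77 (−23%) and aortic VTI
×0.63 (−37%) at peak strain, stroke volume ×0.74 (−26%), MAP ×1.04 (+4%),
with recovery rebounds of +32% (carotid) and +115% (aortic) relative to T2.
The heart-rate multiplier is **not** an independently published number: it
is set to 1.21 so that the DSI change is 1.21/0.77 − 1 ≈ +57%, the published
DSI effect; the implied +21% heart-rate rise is arithmetic inference, not a
measured datum. Similarly, the shock index's +20% rise is encoded by giving
the profile an explicit SBP trajectory (baseline 119 mm Hg, hold multiplier
1.21/1.20 ≈ 1.0083). A derivation of SBP as MAP plus a fixed pulse-pressure
offset was considered and rejected: with MAP ×1.04 it forces an SI change of
about +17%, inconsistent with the +20% effect the profile is meant to
encode.

Beat morphology uses a piecewise arterial pulse: a quarter-sine systolic
upstroke peaking at `systolic_rise_fraction` of the cycle, an exponential
diastolic decay pinned to end at the end-diastolic velocity, and an optional
Gaussian dicrotic notch. A symmetric `"halfsine"` mode exists purely as an
analytic oracle (cycle integral `2·Vp·T/π`). Defaults — carotid PSV
100 cm/s, EDV 20 cm/s; aortic PSV 100 cm/s, EDV 5 cm/s — are typical adult
values; the aortic EDV is kept slightly above zero so diastolic frames
retain signal and are not masked. Per-beat jitter is multiplicative
log-normal (RR sd 2%, VTI sd 3%); inter-subject scatter on responder
multipliers is log-normal sd 5%; sham controls draw their programmed aortic
effect uniformly in ±8%, keeping a deliberate margin from the 10% decision
boundary, with the carotid effect scaled by the responder carotid/aortic
ratio (23/37). All of these are configurable; the values are stated here
once and used everywhere.

Beats share one set of onsets across channels (one heart). Each beat's
duration is set by the heart-rate trajectory at its onset; the waveform
amplitude is scaled by `vti_multiplier × hr_multiplier` because compressing
a fixed shape in time shrinks its area — this keeps the *programmed* number
the true per-beat VTI scale.

## Doppler audio synthesis

Velocity maps to frequency by the CW Doppler equation
`f = 2 f0 v cos(θ) / c`. Defaults: carrier `f0` = 4 MHz, `c` = 1540 m/s,
insonation angle 0°, audio rate 44.1 kHz — arterial velocities then land in
the audible few-kHz band, as in a real Doppler audio output. The carrier and
angle of the patch are explicit configuration, not inferred facts.

Each channel is a sum of scatterer tones whose instantaneous frequencies are
fixed fractions `u_k` of the envelope's shift, with phases integrated
through time (`phase_k(t) = u_k ∫ 2π f(t) dt`). The fraction distribution
emulates the blunt velocity profile of large central arteries: 70% of
scatterers in the fast core (`u ∈ [0.95, 1]`) and 30% spread uniformly —so
spectral power concentrates just below the envelope edge, where a
95th-percentile tracer should find it. 96 scatterers give converged spectral
statistics at acceptable cost. White Gaussian noise sets the SNR (power
ratio, dB); samples with zero true velocity are gated to silence, emulating
a wall filter. For a fixed seed the output is bit-identical.

What the simulator does **not** emulate: wall filters and clutter,
transducer beam geometry and spectral broadening, bidirectional flow,
aliasing, probe motion, or the internals of the pulse-contour stroke-volume
monitor (only its 20-s output cadence is modeled). Passing tests therefore
demonstrate correctness of the measurement chain under an idealized signal
model, not robustness to every artifact of bedside recordings.

## Envelope tracing

The spectrogram uses a 10 ms Hann window hopped by 2.5 ms — short enough to
resolve systolic upstrokes at heart rates up to ~180 bpm. The FFT length
equals the window length (no zero padding), so the bin width is exactly
`1/window_length` = 100 Hz ≈ 1.9 cm/s at the default carrier; padding would
shrink the nominal bin without adding resolution. Power is scaled as a
one-sided periodogram (`2|X|²/(fs·Σw²)`), Parseval-consistent up to the
DC/Nyquist folding.

The maximum-frequency tracer is an integrated-power-percentile rule: per
frame, the traced frequency is the lowest bin where cumulative
noise-corrected power reaches 95% of the frame total (ties to the lower
bin). The per-frame noise floor is the mean power of the top 10% of
frequency bins, assumed signal-free — valid here because the largest shifts
(~7 kHz) sit far below Nyquist (22.05 kHz). Frames whose raw power does not
exceed `power_gate` (default 2) times the extrapolated floor are masked
(velocity 0, quality flag `FALSE`); masked frames propagate downstream, and
beats overlapping them are excluded from window means.

The traced series is median-filtered over 9 frames (22.5 ms). The choice is
deliberate: Doppler spectra exhibit speckle — per-bin power is approximately
exponentially distributed whatever the scatterer count — and a 5-frame
median still lets ~1.5% of frames cross one bin; 9 frames suppresses those
excursions while remaining an order of magnitude shorter than a systolic
upstroke. On noiseless audio from a slowly varying envelope the trace agrees
with truth to within one bin for over 99% of frames; on pulsatile audio the
appropriate accuracy statement is an RMS one (about 1% of peak velocity at
20 dB SNR), because within a single 10 ms window a systolic upstroke moves
by several bins and "the" instantaneous truth of a frame is undefined at
one-bin precision.

## Beat segmentation and VTI

Systolic peaks are local maxima separated by a 300 ms refractory period
(capping detectable heart rate at 200 bpm) and prominent relative to the
median peak prominence. Each onset is the *foot* of the upstroke by the
intersecting-tangent convention: the tangent at the steepest point of the
rise, projected back to the level of the preceding trough. For a
sharp-footed rise this is the derivative maximum itself; on traced
(smoothed) envelopes it removes the systematic delay a raw derivative
maximum would incur. Per-beat VTI is the trapezoidal integral of the
envelope over `[onset_i, onset_{i+1})` on the native frame grid — no
resampling, integration error bounded by the hop length. The final partial
beat is discarded; dropped beats are recorded with the result.

## Statistics and detection

`paired_t_test()` uses differences `d = y − x` (after minus before),
`t = mean(d)/(sd(d)/√n)` with the sample (n−1) standard deviation,
`df = n − 1`, two-tailed p from the t distribution; it is cross-checked
against the reference implementation to 1e-9 in the test suite. No
multiple-testing correction is applied.

`detection_metrics()` calls a subject positive when its percent change
crosses the threshold in the stated direction — *fall* for carotid VTI,
*rise* for DSI and SI. `sweep_thresholds()` evaluates every midpoint between
sorted predictor values and reports Youden's index; the headline
sensitivity/specificity is evaluated at the Youden-optimal threshold.

Reference labels ("did aortic VTI truly fall ≥10%?") default to the
**programmed** effect size of each subject's profile, which is what the
cohort constructor guarantees margins for: responders are programmed far
past −10%, shams within ±8%. Labeling by the *realized* beat-level change is
available (`truth_from = "realized"`) but lets beat-to-beat jitter carry a
borderline sham across the boundary, at which point a "miss" reflects label
noise rather than predictor failure. The primary detection interval is
T1→T2 (peak effect); T2→T3 recovery changes are computed alongside.

## Problem sizes and determinism

The default simulated cohort is 8 responders plus 8 sham controls — the
responder count matches the study design the presets are calibrated to, and
the controls make specificity measurable. Sixty-second two-channel
recordings at 44.1 kHz process through the full pipeline in roughly 15–20 s
per subject on a single core; the test-suite fixtures use shorter records
where the full protocol is not needed. Every stochastic step takes an
explicit integer seed; per-subject seeds derive deterministically from the
master seed, audio is bit-identical under a fixed seed, and two
`run_pipeline()` runs with the same configuration produce bitwise-identical
CSV outputs.

## Known limitations

* The simulator's spectra are stylized (no clutter, no spectral broadening
  from beam geometry, no direction separation); envelope-tracer accuracy on
  real patch audio will be worse than on synthetic audio.
* The heart-rate (+21%) and SBP (+0.8%) hold multipliers are arithmetic
  inferences that make the DSI (+57%) and SI (+20%) effects close, not
  independently published measurements.
* Per-beat VTI on a 5 ms truth grid carries ~0.5% quantization wobble;
  window means average it out, but single-beat comparisons should use the
  stored ground-truth beat table rather than re-integration at coarser
  grids.
* The detection analysis reproduces perfect separation *under the simulated
  effect sizes and jitter*; it is a consistency check of the pipeline, not
  clinical evidence.
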