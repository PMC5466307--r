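---
title: "Measuring end-systole per heart beat and personalising its prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring end-systole per heart beat and personalising its prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsystole)
```

## The problem

Retrospectively gated cine MRI assembles k-space lines acquired over many
heart beats into one representative cardiac cycle. To place a line acquired
at time $t$ after the R wave into the mean cycle, the reconstruction must
know where systole ended in *that* beat. Since no per-beat measurement is
normally available, reconstructions predict end-systole from heart rate with
a global population regression (Weissler's formula, from phonocardiographic
S1–S2 intervals measured half a century ago). A global model cannot follow
individual physiology — medication, pressure, diurnal and pathological
effects all shift systolic intervals — and its errors smear exactly the
mid-cycle features (early-diastolic filling) that high-temporal-resolution
imaging is after.

`rtsystole` implements the alternative: measure end-systole on *every* beat
of a short real-time phase-contrast (RTPC) scan that repeats only the
central k-space line, and fit a per-subject linear law

$$ S = \beta_0 + \beta_1 \cdot \mathrm{HR}, $$

the *patient-adapted cardiac model* (PACM), with $S$ the delay (s) from the
R wave to the end of forward systolic aortic flow and $\mathrm{HR}$ the
cycle's instantaneous heart rate (bpm). Because no public raw RTPC data
exist, the package ships a deterministic simulator of the full acquisition
(k-space echo streams, multi-lead ECG, ground truth), so every stage is
testable end to end.

## The measurement pipeline

**Acquisition model.** The RTPC protocol acquires one 256-sample central
k-space line every TR = 6.6 ms with interleaved through-slice velocity
encoding (venc 150 cm/s, FOV 350 mm, two receive channels). Each echo's
image-space phase is $\pm\pi v/(2\,\mathrm{venc})$, so the phase
*difference* between adjacent echoes maps $v = \mathrm{venc}$ to $\pi$.

**Reconstruction** (`reconstruct_velocity_map()`): unitary 1D FFT per echo
and channel; crop to the central 50% FOV (128 of 256 pixels); *shared
velocity encoding* — every sliding pair of adjacent echoes yields one
velocity frame, so frames are spaced one TR (6.6 ms), not two; channels are
combined as the magnitude-weighted mean. A frame is timestamped at its echo
pair's midpoint, because the phase difference measures the average velocity
of the two instants. No image-based velocity-offset correction is applied:
a constant encoding-locked phase offset passes through linearly to velocity
(this pass-through is asserted by a test).

**Segmentation** (`segment_aorta()`): the 1D+t velocity image is decomposed
by SVD; pixels whose temporal-energy-weighted loading
$\max_i \sigma_i |u_i(x)|$ reaches 25% of the global maximum form the vessel
mask; contiguous runs become ROIs; each ROI's mean-velocity course is scored
by its periodogram power in the cardiac band (subject mean heart frequency
± 0.03 Hz); ROIs with more than 40% of the maximum band power *and* positive
mean flow are candidates; the largest candidate (ties: lowest pixel index)
is the ascending aorta. The threshold is applied against the *global*
loading maximum rather than per component: a per-component threshold would
let a noise-only third component inject arbitrary pixels, since its own
maximum is itself noise. The whole chain uses one set of defaults for all
subjects — no per-subject tuning.

**ECG processing** (`analyze_ecg()`): a per-subject QRS template (mean of
120 ms windows around the online detections) is slid within ±50 ms of each
online detection; the refined R time is the correlation maximum summed over
leads. Cycles are screened: instantaneous heart rate outside 30–120 bpm
rejects the cycle; an RR differing by more than 20% from *both* the
full-record median RR and the previous RR marks an ectopic beat and rejects
the cycle and both neighbours. The median is computed once over the whole
record, which makes screening idempotent.

**End-systole detection** (`measure_systole()`): the S wave is each
accepted cycle's velocity maximum; the baseline is estimated in 10
iterations — a 0.5 Hz zero-phase low-pass initialises it, then histogram
analysis clamps extreme values to the current baseline with the threshold
lowered by one discrete interval per side per iteration; end-systole is
where the falling S wave first meets the baseline, refined by linear
interpolation between the bracketing frames. Durations outside 100–500 ms
are discarded as non-physiological.

The baseline's histogram intervals are anchored on the histogram *mode*:
the diastolic plateau is by far the most populated velocity value, so the
mode bin is the natural anchor, and `n_iter + 1` equal intervals span from
it to each data extreme. Anchoring at the raw min/max instead (with, say,
64 fixed bins) provably cannot work for a one-sided pulse: ten one-bin
steps never reach past the systolic lobe, and the bottom clamp erases the
diastole that anchors zero flow. With mode anchoring the final kept band is
exactly the mode bin, and on clean pulsed courses the baseline settles
within a fraction of a percent of the true diastolic level.

## The model layer

`fit_pacm()` fits a robust linear regression (Huber M-estimator, tuning
1.345, via IRLS) of measured systole duration on the cycle's own
instantaneous heart rate, over the chronologically first 80% of a subject's
valid cycles (`split_train_holdout()`, floor per subject); the last 20% are
held out for validation. The quality metric is the SD of the residuals
(denominator $n-2$): above 10 ms the subject is excluded. $R^2$ is
deliberately *not* the gate — a subject with nearly constant systole
duration has near-zero $R^2$ under a perfectly good constant model. With
zero heart-rate variance the fit degrades gracefully to slope 0 and a
robust location intercept.

`fit_population_model()` applies the same regression to the pooled cycles
of one sex ("PACM averaged"). A pooled per-cycle $R^2$ and an $R^2$ on
subject-mean points answer different questions (within- vs between-subject
explained variance), and a per-cycle regression with residual SD ~0.02 s
cannot reach $R^2 = 0.96$ at the observed heart-rate spread; both variants
are therefore reported (`r_squared`, `r_squared_subject`) rather than
guessing which one a published table meant. `weissler_model()` exposes the
historical global constants (M: $0.456 - 0.0018\,\mathrm{HR}$;
F: $0.461 - 0.0016\,\mathrm{HR}$; SD 0.014 s); the echocardiographic row
(`reference_model("echo")`) is a simulator preset only — its systole
definition (isovolumetric contraction to relaxation) differs from the end
of forward aortic flow, so it is never used as validation truth.

## Evaluation layer

`bland_altman()` reports bias, ±1.96 SD limits of agreement, the SE of the
bias and a one-sample t-test. `compare_models()` predicts end-systole on
holdout cycles from each model and compares biases with paired t-tests.
Before analysis an outlier screen removes cycles whose difference deviates
from the median difference by more than 4 MAD under any model — the
synthetic analogue of discarding, with logged reasons, beats where the RR
lengthened without a systole change (non-conducted P wave) or the systole
outran its RR (extrasystole). The 4-MAD rule is a design choice; no printed
rule exists for those exclusions.

`biphasic_project()` is the cine time projection: systole $[0, S_i]$
stretches linearly onto $[0, \bar S]$ and diastole $[S_i, RR_i]$ onto
$[\bar S, \bar{RR}]$ — continuous, strictly increasing, bijective.
`reconstruct_cine()` bins projected samples into a mean-cycle course and
records the E-wave peak (maximum in the first third of diastole after
$\bar S$). An end-systole source biased by +30 ms misaligns samples from
different beats and measurably attenuates the E peak; the paired one-sided
Wilcoxon test (`e_peak_test()`, exact for $n \le 10$) mirrors the
small-sample comparison this illustration is meant for. The two-segment
linear form of the projection is itself a design decision: the cine
algorithm it models is published only by reference.

## The synthetic world

The simulator's defaults are the stated acquisition and population:
128 beats, heart rate 67 ± 9.5 bpm within [44, 114], TR 6.6 ms, venc
150 cm/s, two channels, 256-pixel FOV. The default systole law is the male
Weissler line with a 5 ms cycle-to-cycle residual (a good-quality subject
under the 10 ms gate).

Choices the source material does not fix, made once:

* **Heart-rate dynamics.** Instantaneous HR follows a smooth
  heart-rate-variability process — a respiratory-sinus-arrhythmia
  oscillation (period 5 beats, 3.2% of variance), a dominant low-frequency
  oscillation (period 26 beats), and a small AR(1) residual — calibrated so
  the stationary SD equals `sd_hr` exactly, then clipped to `hr_bounds`.
  An i.i.d. truncated-normal draw with SD 9.5 bpm would put roughly one
  beat in six more than 20% away from the median RR, so the screening rule
  would reject a large fraction of perfectly normal beats; real sinus
  rhythm is strongly autocorrelated, and with the smooth process a clean
  record is accepted at 100%, as it should be. The marginal is bell-shaped
  rather than exactly truncated-normal; the regression-recovery targets are
  insensitive to that distinction.
* **Waveform.** The aortic lobe is a half-sine from R + 30 ms to exactly
  R + $S_i$ (peak 100 cm/s, below venc), followed by a 60 ms, −15 cm/s
  dicrotic undershoot at valve closure, then zero diastolic flow. Only the
  end time matters downstream; the undershoot is physiological and anchors
  the baseline's lower clamp. Ectopic beats scale one RR by 0.6, which
  violates both 20% screening criteria by construction.
* **Confounders.** A descending-aorta-like vessel (negative flow, similar
  timing) and/or a smaller delayed positive vessel can share the
  projection; channel sensitivities are two smooth half-FOV profiles.
* **ECG.** A fixed synthetic P-QRS-T template per lead, an MHD bump
  synchronous with the ejection window, Gaussian trace noise, and online
  detections jittered by 10 ms SD (the refinement stage's raison d'être).
* **Seeding.** Every random draw flows from the subject seed through fixed
  per-stage sub-seeds, so any stage reproduces bit-identically in
  isolation. Breathing motion is not simulated.

A green test on this world establishes that the *algorithms* implement
their contracts and recover known truth under realistic noise; it cannot
establish performance on real scanner data, whose flow profiles, coil
behaviour, MHD morphology and artefact structure are richer. In particular
the segmentation's failure modes on real anatomy (vessels aligned with the
aorta in the projection axis) are only represented schematically.

## Numerical choices

* Unitary FFT normalisation (Parseval-clean); spatial axis ordered with
  pixel 1 at the FOV edge.
* The 0.5 Hz low-pass is a 4th-order Butterworth applied forward–backward
  (zero phase) as cascaded biquads, with odd-reflection padding of
  $3 f_s / f_c$ samples — at such low normalised cutoffs a short pad leaves
  multi-second edge transients. The filter runs on the mean-removed signal,
  which makes it exact for constants. No DSP package is assumed; the design
  is ~40 lines and tested against its defining properties.
* Ties: S-wave maxima and correlation maxima take the earliest frame;
  equal-size ROIs take the lowest pixel index.
* Sub-frame crossing times by linear interpolation; a crossing exactly on
  a frame returns that frame time.
* Degenerate inputs: all-zero maps, empty masks, cycles shorter than one
  frame, courses never returning to baseline, and subjects with fewer than
  5 valid cycles all resolve to explicit statuses rather than errors; a
  stage failure downgrades the subject, never the cohort run.

## Scaling of the shipped checks

The cohort-level accuracy checks run the full k-space → reconstruction →
segmentation → detection chain on 32-beat records (50 subjects for the
noise condition) instead of 128 beats: the assertions are per-cycle, so the
record length only sets the sample size, and the shorter records keep the
default test run within a practical time budget. Persistence is plain text
only: a subject "bundle" stores configs and derived tables, and the raw
arrays regenerate bit-identically from the stored seed.

## Known limitations

* Velocity aliasing beyond venc is simulated faithfully but not unwrapped;
  a subject whose aortic velocity exceeds venc would fail quality checks
  rather than be recovered.
* The regressor is the measured cycle's own instantaneous HR; physiology
  suggests the preceding RR also matters, and with strongly autocorrelated
  HR the two are nearly indistinguishable — the choice is exposed, not
  resolved.
* The echo-row constants are generator presets; nothing in the package
  emulates echocardiographic image analysis.
* `process_subject()` assumes the ECG and echo streams share a clock, as
  they do on a scanner and in the simulator; no drift correction exists.
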