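---
title: "Methods: impedance assessment of scalp microcirculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impedance assessment of scalp microcirculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measurement problem

Tissue electrical impedance measured with a tetrapolar electrode array has
two informative components: a slowly varying baseline `Z_base` that tracks
overall blood filling and tissue structure, and a small pulsatile component
(tenths of a percent of the baseline) synchronous with the cardiac cycle,
produced by arterial inflow. Plotted inflow-up (the rheogram convention,
where the physical impedance *drop* on systolic inflow becomes an upward
deflection), each cardiac cycle carries a pulse wave whose amplitude,
shape and timing encode arterial inflow, vascular tone and pulse-wave
propagation. During cardiac surgery these signals — a forehead channel over
the scalp microvasculature, an arm channel dominated by central
hemodynamics, an ECG for cycle delimitation and a laser Doppler flowmetry
(LDF) probe as an independent microcirculation reference — change markedly
across surgical stages, and no signal exists at all during cardiopulmonary
bypass (CPB) or during electrocautery pauses.

`rheomicro` implements this analysis end-to-end, and, because recordings of
this kind are not publicly deposited, ships a synthetic-recording generator
with embedded ground truth against which every stage of the pipeline is
validated.

# The synthetic generator

`synth_config()` / `generate_recording()` emulate the acquisition:

* **Stage protocol.** Five stages; defaults of 25, 60, 9, 81 and 21 s —
  one second per minute of the median published stage durations of the
  emulated intraoperative protocol, preserving relative stage weighting
  while keeping a recording near three minutes. These sizes, together with
  10-subject cohorts, are also the problem sizes used by the test suite
  and the acceptance script.
* **Recording gaps.** A 60 s unrecorded interval between stages 3 and 4
  (CPB) and configurable electrocautery pauses inside stages are
  represented as explicit masked intervals (samples `NA`, plus a mask list
  on every channel), not as noise fill: segmentation must treat them as
  first-class gaps.
* **ECG.** A PQRST Gaussian-component train, 1 mV R amplitude, plus slow
  baseline wander. R-R variability is band-limited: a very-low-frequency
  (0.035 Hz) sinusoidal heart-rate modulation plus a small white term, with
  total coefficient of variation `hr_jitter` (default 0.03). White per-beat
  jitter is deliberately avoided: heart-rate variability is band-limited,
  and in anesthetized, mechanically ventilated patients — four of the five
  stages — vagal respiratory arrhythmia and low-frequency baroreflex
  variability are suppressed, leaving VLF-dominated variability. The
  choice of modulation band matters quantitatively: the amplitude-spectrum
  integral used for the LDF cardiac band has an inherent positive bias
  under frequency modulation (≈1% at 0.035 Hz modulation and 3% CV,
  ≈7% at 0.09 Hz, ≈12% at 0.25 Hz), a property of magnitude-spectrum
  integration, not of this implementation.
* **Pulse kernel.** Each impedance pulse is a lognormal systolic wave
  (peak at `rise` = 0.13 s, log-width 0.45) plus a Gaussian dicrotic bump
  (relative amplitude 0.20, delay 0.33 s, width 0.045 s), delayed from the
  R peak by the channel transit time, smoothly tapered to zero over the
  last 15% of each cycle (venous return), and normalized per cycle so that
  the discrete peak-to-trough equals the configured ΔZ exactly. The shape
  was chosen to exhibit every fiducial the metric battery needs (foot,
  steep upslope, systolic peak, descending limb, dicrotic notch); the
  source waveform literature shows morphologies without a generative
  model, so the kernel parameters are plausible but uncalibrated, and the
  same defaults are used for both channels.
* **Ground truth.** Per visible cycle: ΔZ and mean `Z_base` (exact), the
  intersecting-tangent foot (RTT), dZ/dt-peak latency and the B→X
  ejection interval measured on the noise-free waveform by direct
  independent code. A smooth pulse has no unique "first instant", so the
  configured kernel onset is reported separately (`onset_*`) from the
  operational tangent-foot RTT. Per stage: true LDF mean and cardiac
  amplitude.
* **LDF.** Mean microcirculation level plus a cardiac sinusoid
  phase-locked to each cycle, with multiplicative stage effects.
  Stage-effect defaults follow the qualitative intraoperative pattern
  (pulsatility rising toward mid-surgery, impedance pulse amplitude
  falling markedly after bypass) without claiming to reproduce patient
  values.
* **Cohorts.** `generate_cohort()` draws per-subject physiology uniformly
  within physiological ranges (forehead ΔZ 50–150 mOhm, baseline 80–150
  Ohm, heart rates spanning roughly 60–100 bpm, head circumference 54–61
  cm, tissue thickness 3–4 mm) and jitters stage effects per subject;
  `share_stage_effects = TRUE` applies one subject-level stage modifier to
  both impedance and LDF amplitudes, giving the two modalities a common
  intraoperative trajectory — the construction used to demonstrate the
  stage-averaging correlation contrast.

What the generator does **not** emulate: electrode–skin contact physics,
electrosurgical interference waveforms, non-pulsatile flow during CPB,
motion artifacts with realistic morphology, or respiratory components of
the arm channel. Passing recovery tests on this cohort therefore
demonstrates correctness of the measurement pipeline, not robustness to
every artifact class of a real operating room.

# Segmentation

`split_pulsatile()` reproduces the hardware baseline/pulsatile separation
in software: zero-phase Butterworth filters (order 2 forward–backward,
odd-reflection padding to suppress DC start-up transients), low-pass below
0.3 Hz for the baseline and 0.3–20 Hz band-pass for the pulsatile
component. The cutoffs follow standard rheography practice; the source
protocol states none.

`detect_r_peaks()` is a faithful Pan–Tompkins implementation: 5–15 Hz
zero-phase band-pass, five-point derivative, squaring, 150 ms
moving-window integration, adaptive dual signal/noise thresholds with a
200 ms refractory period and a search-back pass at half threshold after
1.66× the running R-R average, with final refinement to the band-passed
ECG maximum. Masked intervals are processed as independent segments.

`extract_cycles()` forms one half-open window per consecutive R-peak pair
and rejects windows with R-R outside 0.33–2.0 s, windows overlapping any
mask, forehead pulse amplitudes above 3× the 30 s neighbourhood median
(motion artifact) or below a 1 mOhm noise floor. Stage attribution uses
the starting R peak, which is unambiguous for cycles straddling a
boundary. All thresholds are configurable; the source protocol names the
filtering step without quantifying it.

# The metric battery

Derivative-based fiducials are extracted after a zero-phase 20 Hz low-pass
of the pulsatile channels (white noise would otherwise dominate dZ/dt).
Numerical conventions, chosen where the source defines a quantity only by
name:

* **RTT**: intersecting-tangent foot — horizontal tangent at the
  pre-upslope minimum crossed with the maximum-upslope tangent. Standard
  and noise-robust; whether the original transit time was measured to the
  foot or to the dZ/dt peak is unstated, so both `rtt` and `t_ad` are
  reported.
* **LVET**: B point = last crossing of 1% of the dZ/dt maximum before that
  maximum (a pure zero-crossing on a flat pre-systolic baseline is
  numerically unstable under smoothing); X point = global post-peak
  minimum of dZ/dt.
* **α**: arctangent of the mean slope of the ΔZ-normalized descending limb
  from the systolic peak to 63% decay (configurable fraction), in degrees.
* **S_Z** integrates above the cycle minimum, making it offset-invariant.
* **RI** = ΔZ/(1000·Z_base) with the explicit mOhm→Ohm conversion; the
  identity RI·Z_base·1000 = ΔZ holds exactly by construction.

**Volumetric blood filling.** The conversion from pulse impedance to
absolute perfusion uses the classical cylindrical-conductor
impedance-plethysmography relation
`dV_beat = k · ρ · L² / Z_base² · ΔZ`, scaled by heart rate and the sensed
tissue mass to mL/min per 100 g. Defaults: blood resistivity ρ = 135
Ohm·cm, inter-electrode distance L = 2.5 cm, sensed mass ≈ 20 g (≈54 cm²
of scalp × 3.5 mm superficial tissue × 1.05 g/cm³), calibration k = 2.
The exact published conversion model for this probe geometry is not
available; this package therefore implements the classical model with
every parameter exposed, calibrated once so that physiological inputs land
inside the normal skin-perfusion range of 1–8 mL/min per 100 g. dV is
linear in ΔZ and heart rate and inverse-quadratic in Z_base; these
invariants are tested.

**LDF cardiac band.** `mc` is the 10 s epoch mean; the amplitude spectrum
uses a Hann window with amplitude-density normalization, 4× zero-padding,
and calibration against the numerically computed continuous Hann kernel
mass, so that a pure tone of amplitude A integrates to A over the band
regardless of bin alignment (verified to ≤0.5%, with two-tone additivity).
`a_mc` integrates the density over 0.6–1.6 Hz by the trapezoid rule.
Epochs slide at 1 s steps; each cycle inherits the epoch centred nearest
its R peak (whether the original analysis computed the band amplitude per
cycle or per epoch is unstated; epochs give the 0.1 Hz resolution the
band requires).

# Statistics

Stage summaries report median, linearly interpolated quartiles, mean and
sd, with a two-sided Mann–Whitney U test against the previous stage
present in the data (stage 4 is compared with stage 3 across the CPB gap);
the exact test is used for combined n ≤ 20 without ties, the tie-corrected
normal approximation otherwise. Correlations are pairwise-complete
Pearson; stage-averaged correlations reduce each parameter to per-stage
means (within subject, then across subjects) before correlating the five
stage points. Cohort heatmaps take element-wise mean and sample (n−1) sd
across per-subject whole-record matrices, with a stability mask at
sd < 0.15. Artifact-rejected cycles leave `NA`s that are excluded
pairwise, so one bad channel never poisons another parameter.

NMI uses 16 equal-frequency bins per parameter (collapsed bins are
flagged), natural-log entropies and the average-entropy normalization
`MI/((H(X)+H(Y))/2)`; equal-frequency binning makes it invariant under
strictly monotone transforms, which the tests verify. The finite-sample MI
bias for independent data, ≈(B−1)²/2N nats, is ≈0.011 nats at B = 16 and
N = 10⁴, well below the 0.05 NMI independence bound used in tests.

# Clustering

Parameters form four functional groups: forehead impedance, arm impedance,
cross-channel (ΔtZ, ICP, RZ) and LDF. Volumetric blood filling is a
forehead-channel quantity and defaults to group 1 (`dv_in_group3` switches
it, since a case can be made for either). Features are standardized per
column; the surgical stage enters as five unscaled one-hot indicators.

DBSCAN is implemented in the package (no suitable implementation exists
among the declared dependencies) with the sklearn core-point convention
(neighbourhood includes the point itself) and is cross-checked in the
tests against an independently coded fixed-point-expansion oracle and
against a reference implementation when one is available on the host.
Hyperparameters are selected by exhaustive grid search — eps over the
10th–90th percentiles of 4-NN distances, `min_samples` 3–10 — maximizing
the mean silhouette over non-noise points among configurations with ≥2
clusters and ≤20% noise, with deterministic ties toward smaller eps then
smaller `min_samples`. All of these rules are package choices (the source
names only silhouette maximization); each is configurable. One caveat
found during validation and encoded in the tests: a single isotropic
Gaussian cloud almost always admits a weak dominant-core-plus-fringe
partition under this grid (silhouette ≲ 0.45), so "no structure" cannot be
inferred from cluster count alone — genuine group structure shows
silhouettes well above that fringe level. t-SNE (perplexity 30, fixed
seed, auto-reduced with a warning below 3·perplexity+1 rows) is used for
visualization only, never for clustering.

# Pipeline and reproducibility

`run_pipeline()` chains the stages from one config (YAML/JSON or R list)
and one seed into a delimited-text artifact bundle plus a JSON manifest;
every stochastic step derives its seed from the global one, and identical
config + seed give byte-identical numeric outputs (tested). Default
problem size — 10 subjects × ~3.5 minutes × 6 channels at 500 Hz, ~2300
cycles — runs in well under two minutes on one core.

# Known limitations

* The dV conversion is a classical-model stand-in with a declared
  calibration constant; absolute values are physiologically plausible but
  not validated against a reference perfusion measurement.
* The amplitude-spectrum integral A_MC carries a small positive bias under
  heart-rate modulation (see above); estimates are accurate to ~2–3% under
  the VLF variability modelled here, degrading if variability moves into
  faster bands.
* Artifact rejection is amplitude- and duration-based only; waveform-shape
  plausibility checks would be needed for real operating-room data.
* The generator's pulse morphology is shared between forehead and arm
  channels; channel-specific morphology differences (and hence α or LVET
  contrasts between sites) are not modelled.
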