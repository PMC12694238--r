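# rheomicro

Per-cardiac-cycle analysis of scalp microcirculation from synchronized
**bioimpedance (rheography)**, **ECG** and **laser Doppler flowmetry (LDF)**
recordings, of the kind acquired intraoperatively during cardiac surgery
with cardiopulmonary bypass (CPB). The package is aimed at biomedical
signal-processing researchers who want a tested, reproducible pipeline for
this measurement modality: because patient recordings of this type are not
publicly deposited, it ships a first-class synthetic-recording generator
with embedded ground truth, and every processing stage is validated against
it.

## What it computes

A recording has six synchronized channels at 500 Hz: one ECG channel (mV),
two tetrapolar impedance channels — forehead and arm — each hardware-split
into a baseline component *Z*<sub>base</sub> (Ohm) and a pulsatile
component (mOhm), and one LDF microcirculation-index channel (perfusion
units). Five surgical stages are annotated; no signal exists during CPB
(between stages 3 and 4) and during electrocautery pauses.

Cycles are delimited by R-R intervals from Pan–Tompkins QRS detection.
Per cycle and channel the package computes the rheographic battery:

| quantity | definition |
|---|---|
| ΔZ | pulse impedance amplitude, *Z*<sub>max</sub> − *Z*<sub>min</sub> (mOhm) |
| S<sub>Z</sub> | area under the pulse curve above the cycle minimum (mOhm·s) |
| RI | rheographic index, ΔZ / *Z*<sub>base</sub> (dimensionless) |
| A<sub>d</sub>, t<sub>Ad</sub> | maximum of dZ/dt and its latency |
| RTT | R peak → pulse foot (intersecting-tangent method) |
| α | pulse fall angle on the forehead descending limb |
| LVET | B→X interval of dZ/dt on the arm channel |
| ΔtZ, ICP, RZ | RTT difference, ΔZ ratio and *Z*<sub>base</sub> ratio between channels |
| dV | volumetric blood filling, k·ρ·L²/Z²<sub>base</sub>·ΔZ·HR·100/m (mL/min per 100 g) |
| MC, A<sub>MC</sub> | LDF epoch mean and cardiac-band (0.6–1.6 Hz) amplitude-spectrum integral |

Downstream statistics mirror the standard intraoperative analysis: stage
summaries (median, quartiles, Mann–Whitney tests against the previous
stage across the CPB gap), within-stage and stage-averaged Pearson
correlation matrices, cohort mean/std correlation heatmaps with a
stability mask, a normalized-mutual-information matrix (equal-frequency
binning), and DBSCAN clustering of four functional parameter groups with
silhouette-maximizing hyperparameter selection and t-SNE visualization.

## Worked example

```r
library(rheomicro)

rec <- generate_recording(synth_config(seed = 8))
rec
#> <subject_recording> synth_8: 128000 samples @ 500 Hz, 5 stage(s), with ground truth

peaks <- detect_r_peaks(rec$channels$ecg)
length(peaks)
#> [1] 229

tab <- compute_cycle_metrics(rec)
head(tab[, c("stage_id", "heart_rate", "dz_forehead", "rtt_forehead",
             "lvet", "dv", "mc", "a_mc")], 3)
#>   stage_id heart_rate dz_forehead rtt_forehead  lvet    dv     mc  a_mc
#> 1        1     72.115     100.390        0.196 0.180 5.086 11.999 1.248
#> 2        1     71.942     100.492        0.197 0.162 5.078 11.999 1.248
#> 3        1     72.289     100.205        0.199 0.178 5.086 11.999 1.248

stage_summary(tab, "dv")[, c("stage_id", "n", "median", "q1", "q3", "p_vs_previous")]
#>   stage_id   n median    q1    q3 p_vs_previous
#> 1        1  30  5.088 4.953 5.205            NA
#> 2        2  61  4.610 4.455 4.694         0.000
#> 3        3   9  4.504 4.467 4.605         0.171
#> 4        4 100  3.662 3.579 3.775         0.000
#> 5        5  25  1.897 1.846 1.954         0.000
```

The generator produced a subject with a 100 mOhm forehead pulse; the
detector found every visible beat, the per-cycle table recovers the pulse
amplitude within a fraction of a mOhm, and the stage summary shows the
expected intraoperative trajectory: volumetric blood filling of ~5 mL/min
per 100 g before anesthesia, a significant fall after bypass (stage 4) and
a further fall at the end of surgery, with the Mann–Whitney column flagging
each significant transition.

The full cohort pipeline (generation → segmentation → metrics → statistics
→ clustering → report bundle) runs from one call or from the shell:

```r
run_pipeline(NULL, out_dir = "out", seed = 1)        # 10 subjects, defaults
```

```sh
Rscript scripts/run_pipeline.R --out out --seed 1 [--config cfg.yaml]
```

and writes delimited-text artifacts (feature table, stage summaries,
correlation and NMI matrices, cluster results, t-SNE coordinates) plus a
JSON run manifest. Identical config and seed give identical outputs.

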