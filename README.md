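# ppgaf — atrial fibrillation detection from wrist photoplethysmography

Atrial fibrillation (AF) makes the heartbeat irregularly irregular. A
wrist photoplethysmogram (PPG) shows one optical pulse per conducted
beat, so the pulse-to-pulse interval (PPI) series carries the same
irregularity the ECG RR series does. `ppgaf` implements an end-to-end
AF screen for wrist PPG + triaxial accelerometer (ACC) recordings, for
researchers developing or stress-testing interval-based arrhythmia
detectors:

1. **Quality gating** — exclude windows that clip at the saturation
   ceiling, miss > 5% of samples, or carry > 0.5 of their spectral
   magnitude above 30 Hz; exclude segments overlapping any 1-s ACC
   window with weighted motion score
   `0.57·sd(ax) + 0.58·sd(ay) + 0.57·sd(az) > 23.12`, containing a
   PPI < 60/200 s, or tripping the sharp-peak ratios
   (max/med ≥ 4.5 ∧ IQR/med ≥ 2.15 ∧ mean/med ≥ 1.3).
2. **Conditioning** — smoothing-spline baseline removal (10 effective
   df per 10-s window) and denoising (100 df), then peak detection
   (minimal spacing 50/512 s, two-stage sub-sample apex refinement)
   and segmentation into blocks of N = 10/25/40/80 intervals.
3. **Features** per segment: SD, RMSSD, Shannon entropy
   `−Σ P_b log P_b` at B = 10/100/1000 bins, rolling three-segment
   statistics (SD3, RMSSD3, MaxFFTSD3), pulse-morphology features
   (peak-height SD/RMSSD/IQR and their autocorrelation summaries), and
   ectopy features (lag-1/lag-2 PPI autocorrelation, Hartigan dip-test
   p-value, even/odd-position interval SDs).
4. **Classification** — linear SVM (cost 0.1) on the 8 base features,
   with an escalation ladder (RBF kernel → + ectopy features → random
   forest) for cohorts contaminated with premature ventricular/atrial
   complexes; patient-wise 5-fold or within-subject chronological
   validation; ROC/AUC with DeLong 95% CIs.

Because no public dataset pairs wrist PPG, ACC and beat-level rhythm
annotations, the package includes a tested synthetic cohort generator
(`make_dataset()`) producing SR / AF / bigeminy / PAC recordings with
ground-truth beat times, plus baseline wander, noise, motion episodes,
saturation and dropouts. The dip statistic is implemented in the
package and validated against a linear-programming oracle.

## Worked example

```r
library(ppgaf)

cfg <- dataset_config(n_patients = 8,
                      block_plan = data.frame(kind = c("AF", "SR"),
                                              duration_s = c(240, 240)),
                      fs_ppg = 128)
res <- run_pipeline(cfg, n_beats = 25,
                    model = model_config("LINEAR_SVM"), seed = 7)
res$counts
#> AF SR 
#> 64 68
res$eval
#> <eval_result AUC 0.9952 (95% CI 0.9882-1.0000), 64 pos / 68 neg>
round(unlist(res$metrics[c("sensitivity", "specificity", "accuracy")]), 1)
#> sensitivity specificity    accuracy 
#>        98.4        97.1        97.7
```

Eight simulated patients contribute 132 quality-gated 25-beat
segments (64 AF, 68 sinus). Scored patient-wise out of fold, the
8-feature linear SVM separates AF from sinus rhythm with AUC ≈ 0.995:
at the Youden operating point, 98% of AF segments are flagged and 97%
of sinus segments are passed. A per-feature class comparison is one
call away:

```r
head(univariate_report(res$features), 3)
#>     feature    mean_a       sd_a     mean_b       sd_b      p_value
#> 1    ppi_sd 0.1852088 0.05049896 0.09844482 0.06047928 3.139968e-15
#> 2 ppi_rmssd 0.2615103 0.07124892 0.14769996 0.09350169 1.294653e-12
#> 3      se10 1.9565054 0.18941902 1.46886501 0.54400928 7.093331e-10
```

AF segments show roughly twice the interval SD and RMSSD of sinus
segments (0.185 s vs 0.098 s) and higher interval entropy — the
contrasts the classifier exploits.

A command-line driver is installed with the package
(`exec/ppgaf`): `ppgaf simulate`, `ppgaf features`, `ppgaf run-all`
with flags mirroring the configuration objects.

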