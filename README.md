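# hrvee

Heart-rate-variability-aided activity recognition and energy-expenditure
estimation from wearable sensors.

## What this package is for

A wrist accelerometer alone recognises ambulatory activities imperfectly —
sitting vs standing and walking vs ascending have nearly identical movement
signatures — and it cannot see the energy cost of low-movement states such
as seated recovery after exercise. Both gaps are physiological, and both
show up in the electrocardiogram: the mean R–R interval and mean heart rate
differ systematically between the confused activity pairs. `hrvee` is for
researchers in wearable health analytics who want a complete, tested
implementation of that analysis:

* **Signal processing** — Pan-Tompkins-style R-peak detection on single-lead
  ECG (band-pass 5–30 Hz, derivative, squaring, moving-window integration,
  adaptive threshold, 250 ms refractory period), RR artifact filtering
  (300–2000 ms band), one-minute windowing.
* **Features** — the 31 HRV parameters per one-minute window: time domain
  (mRR, SDRR, mHR, SDHR, RMSSD, NN50, pNN50), frequency domain (Welch PSD
  of the 4 Hz cubic-resampled tachogram; VLF/LF/HF peak frequencies, band
  powers, relative and normalized powers, LF/HF), and nonlinear (Poincaré
  SD1/SD2, ApEn, SampEn, correlation dimension D2, DFA α1/α2, and the
  recurrence measures Lmean, Lmax, REC, DET, ShanEn); plus four
  accelerometer features (RMS, SD, dominant frequency, spectral energy) per
  2-s window, averaged 30-per-minute.
* **Recognition** — five-class activity recognition (SI, ST, WK, AS, RU)
  under leave-one-subject-out cross-validation with a validation subject
  for hyperparameter and feature-count tuning; scenarios I (IMU only),
  II (IMU+ECG), III (IMU + selected ECG), IV/V (ECG only); linear/RBF SVM,
  kNN and a closed-form LDA; Mann-Whitney max-p feature ranking.
* **Energy expenditure** — per-minute kcal/min by OLS
  (`Y = β₀ + β₁X₁ + … + β_KX_K + ε`, `β̂ = (X′X)⁻¹X′Y`) with backward
  elimination at p < 0.05, four model families (single vs activity-specific
  × IMU vs IMU+ECG), per-activity RMSE, and a two-way ANOVA over data type
  and model type.
* **Synthetic data** — a generator emulating the 13-subject, six-activity
  laboratory protocol (ECG-derived RR truth, 128 Hz tri-axial wrist
  acceleration, reference EE from a known generative linear model), at both
  signal level and per-minute feature level, so every stage is testable
  without any recorded data.

## Worked example

```r
library(hrvee)

# simulate one subject's 5-minute sitting bout and analyse it
prof <- subject_profiles(1, seed = 1)[[1]]
rr   <- generate_rr_series("SI", 300, prof, seed = 7)
f    <- hrv_features(window_rr(rr)[[1]])
round(f[c("mRR", "mHR", "RMSSD", "pNN50", "LF", "HF", "SD1", "SampEn", "DET")], 2)
#>    mRR    mHR  RMSSD  pNN50     LF     HF    SD1 SampEn    DET
#> 795.06  75.62  42.38  26.67   0.09   0.25  30.17   1.70  90.71
```

The LF and HF peak frequencies recover the generator's configured
modulation tones (0.095 and 0.25 Hz) to within one spectral bin; the mean
RR sits at this subject's sitting baseline.

The numbered scripts under `analysis/` run the full study on a simulated
13-subject cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # cohort + class-conditional stats
Rscript analysis/02_extract_features.R    # 585 labelled minutes x 35 features
Rscript analysis/03_recognition.R         # scenarios I/II/III/V, LDA + linear SVM
Rscript analysis/04_energy_expenditure.R  # models I-IV, RMSE + two-way ANOVA
```

On the default seed the recognition driver prints (mean fold accuracy ± SD
over 13 LOSO folds, 520 pooled minutes):

```
 scenario classifier accuracy    sd
        1        lda    80.58  7.51
        2        lda    84.23  7.24
        3        lda    85.96  5.82
        5        lda    61.73 11.38
```

i.e. adding selected HRV features to the accelerometer (scenario III)
beats both the raw concatenation (II) and IMU alone (I), while ECG alone
(V) resolves the sitting/standing pair but confuses standing with walking.
The mean R–R interval is selected in all 13 folds. The EE driver prints
per-activity RMSE (kcal/min) and the ANOVA: the HRV-aware activity-specific
Model IV averages 0.27 vs 0.52 for the IMU-only single Model I, the
data-type main effect dominates (F(1, 308) = 119.2) and the interaction is
negligible (p = 0.52).

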