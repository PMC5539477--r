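---
title: "Methods: HRV-aided activity recognition and energy-expenditure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRV-aided activity recognition and energy-expenditure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Wrist accelerometers recognise ambulatory activities well, but two failure
modes persist: activity pairs with near-identical movement signatures
(sitting vs standing; walking vs ascending) and energy expenditure (EE)
during low-movement, high-cost states such as post-exercise rest.  Both
failures have a physiological remedy: the heart works differently in the
confused states even when the wrist does not.  `hrvee` implements a
complete analysis around that idea: 31 heart-rate-variability (HRV)
parameters per one-minute ECG window and four accelerometer features per
2-s window feed (a) five-class activity recognition under
leave-one-subject-out (LOSO) cross-validation with rank-test feature
selection, and (b) four linear EE model families crossed over data type
(IMU vs IMU+ECG) and model type (single vs activity-specific).

Because no recorded cohort ships with the package, a synthetic-data module
emulates the laboratory protocol end to end: 13 subjects; sitting (SI) and
standing (ST) for 5 min; walking (WK), ascending (AS) and running (RU) for
10 min; 5 min of seated rest (REST) directly after running; ECG-derived RR
ground truth; tri-axial wrist acceleration at 128 Hz; per-minute reference
EE in kcal/min from a known generative linear model.

## The synthetic generator: what it emulates, and what it does not

**RR intervals.**  Beat-to-beat intervals are a stationary baseline mean
plus two sinusoidal modulations — one in the LF band (0.095 Hz) and one in
the HF band (0.25 Hz) — plus white jitter, clamped to (0.3 s, 2.0 s).  The
sinusoidal law was chosen over an AR or integral-pulse model because it
gives the frequency-domain stage a *known spectral truth*: the band peak
frequencies of the analysed tachogram must recover the configured tones to
within one Welch bin, which is asserted in the tests.  Class means and
dispersions for SI/ST/WK/AS follow the class-conditional window statistics
of the emulated protocol (mean RR 0.86/0.77/0.61/0.47 s, SD
0.12/0.10/0.08/0.07 s; mean HR 71.2/79.9/100.8/130.6 1/min).  RU and REST
have no reported statistics: RU is set to 0.40 s continuing the dynamic
ordering, and REST's *baseline* decays exponentially (time constant 90 s)
from the preceding dynamic activity's mean toward the sitting mean —
seated posture with an elevated, recovering heart rate.  Its configured
window mean (0.735 s) is the midpoint of SI and WK; both values are
documented extrapolations, not protocol facts.

**ECG.**  A fixed-width (~80 ms) biphasic QRS template — a narrow positive
Gaussian spike with a smaller trailing negative lobe — is placed at each
R time, plus optional 0.25 Hz baseline wander and white noise.  This is the
simplest waveform with one unambiguous maximum per beat, so detector
sensitivity/precision can be scored against stored truth at ±20 ms.  P and
T waves, respiratory coupling, electrode drift and dropout are deliberately
out of scope: passing tests say the detector handles *this* morphology
plus noise, not every clinical recording.

**Accelerometer.**  Static activities are gravity plus low-amplitude white
noise; dynamic activities superimpose a gait-frequency sinusoid
(1.8/2.0/2.5 Hz for WK/AS/RU), a second harmonic, and an elevated mean on
the vertical axis, with amplitudes ordered WK < AS < RU and the WK/AS pair
kept close — that overlap, and the SI/ST overlap, are precisely the
confusions the recognition scenarios probe.  The vertical pedestal scales
with amplitude so the vector-magnitude signal keeps its dominant spectral
line at the gait frequency (a zero-mean oscillation would frequency-double
under the magnitude nonlinearity).

**Reference EE.**  Ground truth is an affine function of each minute's
true generative features with separate static/dynamic coefficient sets and
homoscedastic Gaussian noise (SD 0.25 kcal/min) — matching the OLS
assumptions of the fitted models.  Both categories load on mean heart
rate, so HRV-aware regressions genuinely have signal to find, and REST
differs from SI only physiologically, not kinematically.  Defaults give
roughly 1 kcal/min seated and 4–8 kcal/min running.

**Two levels of simulation.**  `generate_cohort()` produces raw signals
and runs through the full extraction stack; `simulate_feature_cohort()`
draws the per-minute feature table directly from the class-conditional
distributions (subject-level and window-level variance in equal shares,
the 29 uninformative HRV parameters as standard-normal noise).  Monte-Carlo
studies (feature-selection recovery over 100 cohorts, scenario and model
orderings over 20–100 seeds) run on the feature level; the signal level
backs the structural and detector tests and the acceptance computation.
Problem sizes in the shipped tests — 13 subjects, 40–45 minutes each,
100-seed replicates — were chosen to make each suite complete in a few
minutes on one core.

## HRV parameters: definitions and numerical choices

Time domain uses the sample-SD (N−1) convention throughout, since the
conventional parameter definitions do not pin one down.  `pNN50`
normalises NN50 by the number of RR intervals.

**Frequency domain.**  The tachogram (interval vs terminating R time) is
resampled to 4 Hz by cubic interpolation, mean-removed, and analysed by
Welch's method: 32-s Hann segments, 50% overlap — documented constants in
the Kubios family of defaults.  Peak frequencies and band powers are
estimator-dependent, so values from other spectral estimators (e.g. AR
spectra) are not directly comparable.
Band powers integrate the PSD over VLF (0–0.04 Hz), LF (0.04–0.15 Hz) and
HF (0.15–0.4 Hz) by the trapezoid rule.  Relative powers use the
*band-limited* total (pVLF+pLF+pHF) as denominator, so the three
percentages sum to 100 exactly; normalized units use LF+HF.  One-minute
windows make VLF ill-posed (period ≥ 25 s); the fields are still computed
and the window metadata records the caveat.  Zero total power returns
flagged zeros, never silent ones.

**Nonlinear.**  Poincaré `SD1`/`SD2` are sample SDs of the rotated lag-1
coordinates.  Under that convention the exact relation to RMSSD is
`SD1² = (M·RMSSD² − M·d̄²) / (2(M−1))` with `M = N−1` successive
differences and `d̄` their mean — the familiar `SD1 = RMSSD/√2` only holds
for `d̄ = 0` and population SDs.  Entropies use template length `m = 2`,
tolerance `r = 0.2·SDRR`, Chebyshev distance; ApEn includes self-matches,
SampEn excludes them and restricts m-templates to those with an (m+1)
extension; a constant window returns 0/0 flagged, and `A = 0` returns the
conventional ceiling `−ln(2/((N−m−1)(N−m)))`.  DFA integrates the centred
series and fits RMS residuals about per-box lines over boxes 4–16 (α1) and
17–64 (α2); α2 is flagged missing on windows too short for two long boxes,
the normal case at one minute.  The correlation dimension uses a delay-1
embedding at `m = 10`, Euclidean distances, and fits log C(r) over the
central portion of the radii where 0 < C(r) < 1.  RQA uses `m = 10`, delay
1, `lmin = 2` and threshold `√m·SDRR`; the line of identity is excluded
everywhere.  One boundary effect is worth noting: on an all-recurrent plot
the two corner diagonals have length 1 < `lmin`, so DET is marginally
below 100% (e.g. 99.52% for 30 beats at `m = 10`) — the brute-force oracle
agrees, and the tests assert that exact value rather than an idealised
100.  Every nonlinear measure is checked against an independent O(N²)
enumeration on series up to length 200.

## Recognition design

Folds are LOSO with a validation subject: test subject *i*, validation
subject *i*+1 (wrapping), the remaining 11 train.  The assignment is
deterministic and leakage-free; nothing in the protocol prescribes how the
validation subject is picked, so the simplest reproducible rule won.
Scalers, feature rankings and hyperparameters derive from training
subjects only (the scaler question — per-subject vs per-fold normalisation
— is genuinely ambiguous in the source protocol; per-training-fold is the
default here, and rank-based selection is scale-invariant either way).

Feature selection computes two Mann-Whitney p-values per HRV parameter —
SI vs ST and WK vs AS, the two pairs an accelerometer confuses — and ranks
by the *larger* p ascending: a feature must separate both pairs.  The
max-p rule is a design choice; it reproduces the expected outcome (mean RR
and mean HR as the top pair) on cohorts with those class statistics.  The
count of selected features is swept 1–8 on the validation subject.  Ties
anywhere resolve to the smallest hyperparameters and fewest features, with
equal p-values breaking by canonical parameter order.

Classifiers: linear and RBF SVM (libsvm via e1071, cost 2⁻⁵–2¹⁵ and gamma
2⁻¹⁵–2³ in powers of four), kNN (k ∈ 1,3,5,7,9), and a pooled-covariance
closed-form LDA implemented in the package so at least one classifier is
fully oracle-testable (it is checked against an established implementation
in the tests).  REST is excluded from recognition and included in EE.

## EE design

OLS is fit by QR decomposition and asserted against the explicit
`(X′X)⁻¹X′y` closed form; per-coefficient p-values are t-based.  Variable
selection is *backward* elimination at p < 0.05 (the criterion is fixed by
the analysis design; the direction is not, and backward is the
conventional reading of "significance in the fitted model"), always
keeping the intercept; eliminating everything returns an intercept-only
model with a warning.  EE folds have no validation subject (12 train / 1
test).  The candidate pool is height, weight and the four IMU features (6)
or those plus the 31 HRV parameters (37).  Activity-specific fits train
one model on static minutes (SI, ST, REST) and one on dynamic minutes
(WK, AS, RU), routed at test time by the ground-truth label — EE is
evaluated given known activity, as a separate experiment from recognition.
Features enter the regressions on their raw scales (coefficients stay
interpretable in kcal/min per unit); the z-scored variant is available but
not the default.  Model comparison pools the fold × activity RMSE cells
(13 folds × 6 activities × 4 specs = 312 cells, error df 308) into a
balanced two-way ANOVA over data type and model type, computed by the
classical sums-of-squares decomposition and cross-checked against
`stats::aov`; a zero effect sum-of-squares reports F = 0 by convention
even when the error mean square vanishes.

## Degenerate inputs, in one place

Constant RR windows: time-domain zeros; flagged zero spectra; zero
Poincaré dispersions; entropies 0 by convention; DFA errors (zero
fluctuation) and is flagged missing by the window assembler; D2 = 0
flagged; RQA fully recurrent.  Zero-variance features: centred, scale 1,
flagged by the scaler.  Sub-300 ms or super-2000 ms intervals: dropped and
counted, never interpolated.  Windows with fewer than 25 of 30 IMU
sub-windows: flagged missing minutes.  All-zero confusion matrices and
rank-deficient designs: errors naming the offender.

## Limitations

The generator's cardiac and kinematic laws are deliberately minimal;
passing tests demonstrate internal correctness of the pipeline and
directional reproduction of the headline orderings (selected-HRV
recognition ≥ IMU-only; HRV-aware activity-specific EE < IMU-only single
EE), not the magnitudes any particular human cohort would produce.  REST
physiology is a stand-in recovery model.  Kubios-compatible artifact
correction, respiration, multi-lead ECG and nonlinear EE models are out of
scope.
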