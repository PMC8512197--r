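---
title: "Screening heart sounds for rheumatic heart disease: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening heart sounds for rheumatic heart disease: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pcgscreen` implements a segmentation-free screening pipeline for rheumatic
heart disease (RHD) from single-channel phonocardiograms (PCG). RHD damages
heart valves; the resulting turbulent flow produces systolic and/or
diastolic murmurs that are audible in the heart-sound signal. The pipeline
never tries to segment the cardiac cycle into S1/systole/S2/diastole —
instead it summarises a whole 30-s record by 31 scalar features and lets a
kernel classifier separate murmur-bearing records from healthy ones. This
vignette explains each stage, the parameters that matter, and the design
decisions taken where several defensible choices existed.

## Preprocessing

Every recording, whatever its source rate, is reduced to a canonical form:

1. **Bandpass 20 Hz–1 kHz**, 4th-order Butterworth applied forward and
   backward (`filtfilt`), so the passband suffers no phase distortion and
   murmur timing is preserved. The same filter is the antialiasing stage
   for the subsequent resampling. Heart sounds and murmurs live well below
   1 kHz; below 20 Hz only motion and baseline artifacts remain.
2. **Polyphase resampling to 2 kHz.**
3. **A single 30-s segment.** The first 30 s are taken (offset
   configurable). Records shorter than 30 s are rejected — an inclusion
   rule, not an error in the data.
4. **Z-scoring** to zero mean and unit variance, which removes the
   (arbitrary) absolute gain of stethoscope recordings.

One degenerate corner needs a rule: for input already at 2 kHz the nominal
1 kHz upper band edge sits exactly at Nyquist, where a Butterworth bandpass
is undefined. `preprocess_record()` clamps the upper edge to 0.49 × rate
(990 Hz at 2 kHz) in that case; `bandpass_filter()` called directly still
refuses `high >= Nyquist`. The canonical record is exactly 60 000 samples;
z-scoring is idempotent, and the whole chain is a pure function of its
input.

## The 31-feature representation

Features are computed on the z-scored record and concatenated in a fixed
canonical order — acoustic (4), frequency (5), time (9), perceptual (13) —
which is part of the CSV format contract.

**Time domain (9).** Median, first/third quartile and IQR (linear
interpolation between order statistics, R's default quantile convention),
mean absolute deviation about the mean, skewness `g1 = m3/m2^1.5`,
non-excess kurtosis `m4/m2^2` (Gaussian = 3), Shannon energy
`-(1/N) sum(x^2 ln x^2)` with `0·ln 0 := 0`, and the zero-crossing rate as
the fraction of strictly sign-changing adjacent pairs. Conventions that
toolboxes disagree on (quantile interpolation, MAD centre, kurtosis offset)
are pinned here so ports can match numerically.

**Frequency domain (5).** A Welch PSD (1024-sample Hamming segments, 50%
overlap, one-sided, ~1.95 Hz resolution at 2 kHz) is normalised to a
probability distribution over non-DC bins — after z-scoring the DC bin
carries nothing. From it: normalised spectral entropy (0 for a line
spectrum, 1 for white); the dominant frequency (ties break to the lowest
frequency, for determinism); its normalised magnitude; the dominant
frequency ratio, defined here as the power fraction within ±5% of the peak
(at least ±1 bin); and the bandwidth as the power-weighted spectral spread
about the centroid. The last two quantities have no universally fixed
definition in the feature-extraction literature; the definitions above are
this package's, chosen to be deterministic and scale-free.

**Perceptual domain (13).** MFCC1–13: 256-sample (128 ms) Hamming frames
with 50% hop, magnitude-squared spectrum, 26 triangular mel filters over
0–1000 Hz, natural log with a 1e-10 floor, orthonormal DCT-II, coefficients
1..13 averaged over frames. The 0th coefficient is excluded: it is a pure
loudness proxy, and overall level is (a) removed by z-scoring and (b)
separately represented by the acoustic loudness feature. 128 ms frames are
long by speech standards but appropriate at 2 kHz, where murmur bands need
~8 Hz resolution. No pre-emphasis is applied — that is a speech-specific
high-frequency boost with no justification for low-frequency heart sounds.

**Acoustic (psychoacoustic) domain (4).** Roughness (asper), loudness
(sone), sharpness (acum) and fluctuation strength (vacil) describe how a
sound *feels* to a listener, and murmurs are precisely what clinicians
*hear*. Psychoacoustic models need sound-pressure input, but stethoscope
recordings carry no absolute calibration, so the package adopts a fixed
convention: the unit-RMS z-scored record maps to 60 dB SPL, then is
upsampled to the 16 kHz model rate. (Level mostly cancels anyway:
sharpness, roughness and fluctuation are approximately level-normalised,
and loudness enters all records through the same convention.) The model
rate of 16 kHz covers the PCG band and all validation stimuli at a quarter
of the cost of a full audio rate.

- *Loudness* follows the Zwicker stationary structure: 64 ms frames,
  power spectra integrated into 1-Bark-wide sliding critical bands on a
  0.1-Bark grid, the Terhardt threshold-in-quiet curve, and the standard
  compressive law `N'(z) = 0.08 (E_TQ/E0)^0.23 ((0.5 + 0.5 E/E_TQ)^0.23 - 1)`.
  Inter-band masking slopes are **not** modelled; the 1-Bark sliding
  integration provides critical-band smoothing. The sone scale is fixed by
  its definition — a 1 kHz tone at 40 dB SPL scores exactly 1 sone — via a
  single internal anchor normalisation.
- *Sharpness* is the DIN-45692-style weighted centroid
  `0.11 ∫ N'(z) g(z) z dz / ∫ N'(z) dz` with the high-frequency emphasis
  `g(z)` rising above 15.8 Bark. It is level-invariant by construction.
- *Roughness* and *fluctuation strength* are driven by envelope modulation
  within critical bands: the signal is decomposed into overlapping
  1-Bark channels (0.5-Bark spacing) by exact frequency-domain band
  selection, each channel's Hilbert envelope is extracted, and the envelope
  modulation spectrum is weighted by a modulation-rate curve peaking at
  70 Hz (roughness) or 4 Hz (fluctuation, the Fastl `(f/4 + 4/f)^-1` law).
  Channel contributions (squared effective modulation depth) integrate
  over the Bark axis. Envelope edges (5% each side) are discarded — the
  circular band selection wraps the record ends into a spurious transient
  — and channels more than 26 dB below the strongest are gated out. The
  cross-channel correlation factors of the full Daniel–Weber model are
  omitted. Each metric is anchored at its unit-defining stimulus (1 kHz,
  60 dB, 100% AM at 70 Hz ≙ 1 asper; at 4 Hz ≙ 1 vacil).

These are deliberately compact re-implementations of the published model
*structures*, not certified implementations of any standard; the test suite
pins the properties that matter for feature extraction (unit anchors,
modulation-rate peaks, level monotonicity, level invariance of sharpness,
near-zero response of unmodulated tones).

## Classifier

A soft-margin SVM with Gaussian RBF kernel `K(x, xi) = exp(-γ ||x - xi||²)`.
The dual problem is solved by libsvm's SMO (via `e1071`), and the solution
is stored as an explicit kernel expansion — support vectors, signed dual
coefficients `αᵢyᵢ`, bias — whose decision function
`g(x) = Σ αᵢyᵢ K(x, xᵢ) + b` the package evaluates itself. The box
constraint `|αᵢyᵢ| ≤ C` and equality `Σ αᵢyᵢ = 0` are asserted in tests on
every fit, and predictions are cross-checked against an independent SVM
implementation (`kernlab`).

Because the 31 features mix units (Hz, sone, dimensionless moments), each
training partition standardises features to zero mean/unit variance using
*training statistics only*; whether the original study scaled features is
unknown, and this choice materially affects the kernel geometry — it is a
documented assumption. Zero-variance features are flagged and left
untouched rather than dividing by zero. The decision threshold is fixed at
0 with ties going to HC; no class weighting is applied (imbalance is
handled by the evaluation protocol, not the loss).

Hyperparameters come from a 5 × 5 grid — C ∈ (0.01, 0.1, 1, 10, 100),
γ ∈ (0.0001, 0.001, 0.01, 0.1, 1) — selected by pooled f1 over the inner
folds. Ties break to the smallest C, then the smallest γ: the smoother
boundary, and deterministic.

## Evaluation protocols

Both protocols operate at the subject level (one record per subject) and
nest model selection strictly inside model evaluation.

**Stratified nested 10-fold.** Outer stratified 10-fold (class proportions
preserved within one subject per fold); each outer training set is again
split into 10 stratified inner folds for the grid search; the winning pair
refits on the whole outer training partition.

**Prevalence-controlled imbalanced protocol.** Screening populations
contain far more healthy controls than cases, so folds are built to a
target prevalence `p`: each evaluation fold holds exactly one RHD subject
plus `round(1/p)` HCs (20 at 5%, 40 at 2.5%). With n RHD subjects this
gives n outer folds (leave-one-RHD-out) and n−1 inner folds per outer
fold. Per repeat, the HC pool splits once into an inner and an outer pool
(half each — both loops need the same number of HC slots per fold); HCs
may recur across folds of the same loop, never within one fold. The final
model for an outer fold trains on all remaining RHD subjects plus the
entire inner pool — every non-test subject contributes while the
evaluation pool stays untouched. Because a single fold contributes at most
one positive, metrics are pooled over all outer folds within a repeat
(per-fold metrics would be degenerate), one metric set per repeat, with
mean ± sd reported over repeats (5 by default). `precision`, `recall`,
`f1` and `specificity` treat RHD as positive throughout; zero denominators
report 0 with an explicit `undefined` flag.

Every plan is fully materialized (subject ids per fold, seeds per repeat)
before any model is fit, and `audit_fold_plan()` re-checks subject-level
train/test disjointness on every run.

## Synthetic data: what it emulates, and what it does not

Clinical heart-sound data cannot ship with a package, so `generate_dataset()`
produces a cohort with the *structure* the analysis assumes: one ≥30-s
record per subject at 2 kHz; S1/S2 as Gaussian-enveloped tone bursts near
60/90 Hz; cycle lengths from 60–100 bpm with 5% jitter; RHD records carry
band-limited (150–400 Hz) murmur noise confined to the systolic and/or
diastolic interval at a controlled energy ratio to S1; and additive noise —
by default "babble" (100–500 Hz noise with slow random amplitude
modulation, imitating people talking) at ~15 dB SNR. Band placements come
from standard auscultation descriptions of heart sounds and murmurs.

Two difficulty presets are fixed: `"separable"` (murmur −6..0 dB re S1,
SNR 12–18 dB), used by the end-to-end tests, and `"hard"` (murmur
−18..−10 dB, SNR −2..2 dB) for robustness checks, with no pass/fail
threshold attached. The generator does **not** model hemodynamics,
recording-chain coloration, borderline-RHD phenotypes, pediatric heart
rates, or pathological sounds other than murmurs. Consequently, passing
end-to-end tests demonstrates that the pipeline's plumbing, features and
protocols behave correctly on data with murmur-like structure — it says
nothing about clinical sensitivity on real patients.

## Numerical choices and problem sizes

- Filters: 4th-order Butterworth, zero-phase; solver tolerance for the SVM
  dual 1e-3 with libsvm defaults otherwise.
- Determinism: every stochastic step (cohort draws, fold assignments, HC
  sampling) flows from explicit seeds recorded in plans and reports;
  repeated runs are bit-identical.
- Degenerate inputs: constant signals are rejected at z-scoring; all-zero
  spectra at frequency features; single-class training sets at the SVM;
  metrics with empty denominators are flagged, not NaN.
- The end-to-end test suite runs the full study-size synthetic cohort
  (124 RHD + 127 HC) with a reduced 3 × 3 grid, 2 repeats of the
  stratified protocol and 1 repeat of the imbalanced protocol at 5% —
  sizes chosen so the complete suite stays comfortably interactive.
  `scripts/acceptance.R` uses a 40 RHD + 68 HC cohort of the same
  conditions with the same reduced grid for the same reason.

## Known limitations

- The psychoacoustic metrics are structural re-implementations; absolute
  values can differ from certified ISO 532-1 / DIN 45692 implementations
  by more than the unit anchors suggest, especially for broadband,
  strongly non-stationary input. Their discriminative value as features is
  what matters here.
- The SPL calibration convention (unit RMS ↦ 60 dB) is arbitrary; loudness
  is therefore a relative, not absolute, descriptor of the recording.
- MFCC hyperparameters (frame length, filter count) have no single
  standard at 2 kHz; the defaults are reasoned but not canonical.
- The stratified protocol's inner fold count (10) mirrors the outer loop
  by choice; other counts are configurable.
- Synthetic cohorts are far easier than clinical data; reported synthetic
  metrics are pipeline health indicators, not expected clinical
  performance.
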