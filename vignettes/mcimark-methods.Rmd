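---
title: "Methods: models, parameters, and design choices in mcimark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in mcimark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

mcimark implements a complete analysis chain for multimodal MCI biomarkers:
channel-wise GLM estimation of task-evoked neurovascular coupling (NVC) from
dual-wavelength fNIRS, surrogate-thresholded total-hemoglobin connectivity
graphs, signal-detection scoring of n-back behavior, FMO-gated
quantification of cerebrovascular endothelial extracellular vesicles
(CEEVs), the accompanying statistics layer, and a LOOCV random-forest
classification protocol. Because the clinical recordings this kind of study
rests on are not publicly available, the package ships a synthetic-cohort
generator whose forward model is inverted exactly by the analysis chain;
all tests and the acceptance script run on such cohorts.

# Signal model and preprocessing

## Optics

A recording holds light intensities I(channel, wavelength, time) at 760 and
850 nm for 48 source–detector pairs separated by 3.0 cm, sampled at 3.9 Hz.
Optical-density changes are ΔOD = −log10(I / mean(I)) per channel and
wavelength. The modified Beer–Lambert law converts ΔOD at the two
wavelengths to chromophore changes by solving, per channel and sample, the
2×2 system

ΔOD(λ) = (ε_HbO(λ)·ΔHbO + ε_HbR(λ)·ΔHbR) · d · DPF(λ),

with d the source–detector separation (cm), DPF the differential pathlength
factor (default 6.0 at both wavelengths; configurable per wavelength — the
literature varies and the value only rescales concentrations), and ε the
bundled molar extinction coefficients (Gratzer/Kollias compilation,
cm⁻¹/mM: 760 nm — HbO 1.4866, HbR 3.8437; 850 nm — HbO 2.5264, HbR 1.7986).
Concentrations are reported in μM. Because the simulator uses the same ε,
d, DPF forward model, MBLL recovery is exact by construction; this is
asserted at < 10⁻⁶ relative error.

## Quality screen

The scalp-coupling score of a channel is the Pearson correlation between
its two wavelengths after band-passing to the cardiac band (0.5 Hz to
min(2.5, 0.95·Nyquist) Hz; at 3.9 Hz sampling the upper edge is ~1.85 Hz).
A shared cardiac pulsation is the classic signature of good optode contact.
Channels scoring below 0.75 (configurable; the threshold is a package
choice, since only the rule's consequences are standard) are poor; a
subject is excluded when more than 80% of montage channels are poor or when
any LDLPFC channel (F3-F5, F3-F1, F3-FC3) is poor. The 80% rule is applied
over all 48 montage channels.

## Two preprocessing branches

* **NVC branch** — OD → spike/step motion correction → MBLL → DCT high-pass
  at 0.009 Hz → (jointly with the GLM design) AR(p) prewhitening, p ≤ 4 by
  AIC on the OLS residuals. The DCT projection removes the basis vectors
  (including the constant) with frequency k·fs/(2N) below the cutoff; the
  same projection is applied to the design matrix inside `firstLevel()` so
  estimates stay unbiased.
* **FC branch** — OD → 5th-order Butterworth band-pass 0.0045–0.4 Hz,
  applied zero-phase (forward–backward, as a high-pass/low-pass cascade;
  series are demeaned first to suppress filtfilt edge transients) → MBLL →
  CBSI → HbT = HbO + HbR. CBSI removes correlated HbO–HbR motion
  fluctuations: with α = SD(HbO)/SD(HbR), HbO′ = (HbO − α·HbR)/2 and
  HbR′ = −HbO′/α, making the corrected pair exactly anti-correlated.

Zero-phase filtering was chosen because the correlation analyses are
phase-sensitive and block timing must not shift. Branch isolation is
enforced by provenance flags: applying the DCT to an FC-branch series (or
the Butterworth/CBSI chain to an NVC-branch series) is an error.

## Motion correction

The paper-level pipelines defer motion handling to toolbox internals; here
it is explicit and simple: samples whose locally detrended robust z exceeds
5 are replaced by cubic-spline interpolation over the (slightly widened)
spike support, and abrupt baseline steps (first difference > 4 robust SDs,
confirmed by a segment-mean offset > 3 robust SDs) are re-leveled. The
offset confirmation keeps clean records bit-identical through the
corrector. Correction can be disabled to run the GLM on raw series.

# First- and second-level GLM

Regressors are 72-s block boxcars convolved with a double-gamma HRF
(response gamma with mode 6 s, undershoot gamma with mode 16 s, ratio 1/6 —
the HRF is a package choice since no canonical form is implied by the
processing chain itself). The kernel is normalized to unit sum, so a
sustained block plateaus at 1 and β is the block-response amplitude in μM.
First-level inference is OLS on AR-prewhitened data per channel and
chromophore; HbO is the headline chromophore, HbR is computed alongside.

Second level: per channel, the mixed model
β ~ −1 + Group:condition + (1 | subject) is fitted by REML (lme4) with one
fixed cell per group-by-condition combination and a subject random
intercept; contrasts are tested with Satterthwaite degrees of freedom
(lmerTest). The cognitive-load contrast uses weights {2b: +1, 1b: +1,
0-back: −2}, with the second 0-back block (0b_2) as the default baseline
(a `zeroBack` switch offers 0b_1 or the mean of both). The FDR family is
the set of channels within one contrast and chromophore; q-values are BH,
significance at q < 0.05. The "session" term of the published formula is
read as the n-back condition label, the only reading consistent with a
four-condition task. The original analyses ran AR-IRLS in a Matlab toolbox;
mcimark implements AR-prewhitened OLS without robust reweighting, a
documented difference.

# Connectivity graphs

Pearson r is computed over each 72-s block window (~281 samples) of the
FC-branch HbT series. Edge significance uses circular time-shift
surrogates: shifting one channel circularly preserves its autocorrelation
(and any sinusoidal physiology) while destroying cross-correlation, so the
null distribution is exact for the block at hand. All shifts are computed
at once via FFT cross-correlation and `nSurr` (default 200, minimum 19 at
α = 0.05) random nonzero shifts are drawn from them; the one-sided p is the
fraction of surrogate correlations ≥ the observed one. Edges are kept only
if p < α and r > 0 (negative correlations are treated as spurious and
zeroed). Retained matrices are also stored as atanh(r*) for Fisher-z
averaging across graphs; scalar degree metrics, by contrast, are averaged
in natural units.

Metrics: Dᵢ (edge count), ʷDᵢ (summed weight); normalized binary values
Dᵢ/(N−1) with global mean D̄; normalized weighted values
ʷDᵢ/((N−1)·max r*) with global mean ʷD̄ — dividing by the graph's maximum
retained edge weight realizes "normalized to the maximum connection
strength" concretely and guarantees [0, 1]. The two published phrasings of
the weighted normalization (maximum strength vs. total possible
connections) are not identical; both are implemented
(`weightedNorm = "maxweight"` default, `"possible"` alternative). LDLPFC
variants average the three LDLPFC channels' normalized node values;
task-averaged variants are arithmetic means over the four block conditions
(available-mean when a block is missing).

# Behavior

Hit rate = hits/targets, false-alarm rate = FA/non-targets; rates of
exactly 0 or 1 are corrected by the 1/(2N) rule before the z-transform
(a log-linear alternative is available). d′ = Φ⁻¹(HIT) − Φ⁻¹(FA). Mean RT
averages correct *responses* only — hits; correct rejections involve no
response and contribute no RT, the only coherent reading for a go/no-go
style response design.

# EV cytometry

Gates are placed per color channel at the 99.9th percentile (configurable)
of the corresponding fluorescence-minus-one control — never from the
stained sample. Sequential gating: CD3/CD41 (pooled channel) positives are
excluded; remaining endothelial (pooled CD31/CD144/CD105) positives are
split by MAL into CEEV (MAL⁺) and MAL⁻ endothelial vesicles; MAL⁺
non-endothelial events form a separate population; labels partition the
table. CEEV ratio = 100·CEEV/(all endothelial). Concentration =
count/volume × dilution with volume = 1.5 μL/min × 120 s = 3 μL. Size bins
are half-open at 180/600/1000 nm. Replicate aliquots (≥ 2 in the protocol)
are averaged arithmetically; single aliquots pass through with a warning.
Spillover compensation is not modeled: synthetic channels are generated
independently given the class label, and the endothelial stain pool shares
one fluor, so a single pooled channel is the faithful representation.

# Statistics layer

Mann–Whitney (exact for both n ≤ 8 without ties, otherwise tie-corrected
normal approximation), mixed two-way ANOVA (group between, task within,
subject error strata; Bonferroni post hocs multiply by the number of task
levels; no sphericity correction by default, matching common
spreadsheet-statistics behavior), Spearman correlation, Fisher's exact
test, BH-FDR, and Cohen's d from summary statistics. The d default is the
rms-SD variant |m₁−m₂|/√((s₁²+s₂²)/2), which exactly reproduces the
published worked value (0.6047) from the printed group summaries; the
pooled variant is available. ROUT, published for nonlinear regression, is
applied to group vectors where the robust regression degenerates to a
constant fit: residuals from the median scaled by a small-sample-corrected
68.27th-percentile robust SD, two-sided t-tail p-values, and a BH step at
rate Q (0.1% default, so false flags are rare by construction).

# Classification protocol

Features per subject: task-averaged LDLPFC NVC β, CEEV ratio, ʷD_LDP,
D_LDP, D̄, ʷD̄, age, sex, hypertension, prior depression; label CN/MCI.
Numeric features are standardized and categoricals one-hot encoded with
parameters fitted on training folds only (verified by a leakage test).
LOOCV random-forest importance: per fold, Gini importances normalized to
sum 1, one-hot columns folded back to their source feature, arithmetic mean
across folds (median available). Top-k selection (k = 3) breaks ties by
fixed feature order. Evaluation: stratified 80/20 splits (stratification is
a package choice to avoid single-class test sets at n = 34), 500 trees,
accuracy plus support-weighted precision/recall and their harmonic-mean F1;
repeated evaluation over 100 splits reports mean ± SD accuracy.

# The synthetic-data generator

`simulateFnirsSession()` is a forward model: ground-truth HbO per channel
is the design-matrix prediction times a group/region amplitude, plus a
shared latent field realizing planted connectivity, physiological
sinusoids (cardiac ~1 Hz, respiration ~0.25 Hz, Mayer ~0.1 Hz) with random
per-channel phases, AR(1) noise, slow drift, and optional motion
spikes/steps; HbR mirrors the vascular components at −1/3 with the
pulsatile component co-varying positively in both chromophores (that
blood-volume signature is what the quality screen measures and CBSI
removes); chromophores are pushed through the extinction forward model to
two-wavelength intensities I = 10^(−ΔOD).

Key defaults and why:

* **Concentration scale.** Task amplitudes ~0.5–2.4 μM over 0.8 μM noise,
  cardiac 0.4 μM. This keeps ΔOD in the small-signal regime of the
  exponential intensity map; it is also the physiological order of
  magnitude for continuous-wave fNIRS. (Published β tables from toolbox
  pipelines can carry different unit conventions; within mcimark β is μM.)
* **Noise spectrum.** AR(1) with φ = 0.95: physiological fNIRS noise is
  1/f-like, and the FC band (0.0045–0.4 Hz) must contain substantial noise
  power or block-level task transients would correlate all channels at
  r ≈ 1.
* **Planted group effects** mirror the direction *and relative strength* of
  the effects this kind of study reports: LDLPFC amplitudes CN
  (0.8, 0.8, 2.0, 2.4) vs MCI (0.6, 0.6, 0.7, 0.7) μM — the CN group mounts
  a load response, the MCI group does not; CEEV fractions 0.055 (CN) vs
  0.125 (MCI), matching published medians of ~5.5% and ~12%; 2-back hit
  probability 0.85 vs 0.65 with slower RTs in MCI.
* **Connectivity.** Channels load on a spatially decaying latent field
  (length scale 12 cm; `Inf` collapses it to a single global latent, in
  which case two channels with weights w₁, w₂ correlate at exactly
  √(w₁w₂)). Coupling weights: CN LDLPFC 0.8 vs MCI 0.55, with all other
  channels at 0.55 in both groups. This keeps LDLPFC edges significant in
  both groups — binary degree stays near its ceiling — while LDLPFC edge
  *strength* drops in MCI, reproducing the reported dissociation (weighted
  LDLPFC degree reduced, global and binary metrics largely preserved).
* **Between-subject variability.** Log-normal amplitude factor (SD 0.2),
  logit-scale coupling jitter (SD 0.15), logit-scale CEEV spread (SD 0.25).
* **Fazekas.** For MCI subjects the white-matter-hyperintensity grade is
  drawn from a binomial(3) probit of the subject's latent CEEV propensity
  (loading 1.3, marginal mean ≈ 1.2), inducing the observed positive
  Spearman association without claiming a mechanistic model.
* **Task design.** Block order 0b_1, 1b, 2b, 0b_2 with 20-s rests
  (configurable; the rest length is not a published constant), 30 letter
  trials per 72-s block, 25% targets.

What the generator does *not* emulate: optics-accurate photon transport,
systemic superficial contamination with its own spatial structure,
realistic letter-sequence psychology, cytometer electronics, fluorescence
spillover. Passing tests therefore demonstrate that the implementation
recovers what it models — they are internal-consistency and calibration
evidence, not clinical validation on real recordings.

# Numerical choices and degenerate inputs

* DCT high-pass at/above Nyquist, invalid Butterworth bands, singular
  extinction matrices, overlapping task blocks, and rank-deficient designs
  are errors naming the offending component.
* Noiseless series skip AR fitting (zero-variance residuals); Yule–Walker
  estimates are stationary by construction, with an AR(1) fallback guard.
* Zero-variance HbR channels pass through CBSI and are flagged.
* The all-zero second-level contrast returns t = 0, p = 1 identically.
* Surrogate thresholding refuses n_surr < 19 at α = 0.05 (p < α would be
  unresolvable); r* = 1 edges are capped just below 1 before atanh.
* Subjects missing an LDLPFC channel are exclusion errors in
  `ldlpfcAverage()`, mirroring the screening rule.
* Random-forest Gini importance is not comparable across feature types
  (continuous features offer more split points than binary dummies), so
  null-behavior checks use exchangeable numeric feature sets.

# Problem sizes used by the test and acceptance suites

Calibration suites run 500 replicates (300 for the channel-wise-FDR null in
the standalone script) with fixed seeds: surrogate retention on
channel-independent blocks, mixed-ANOVA type-I on 8+8 subjects, ROUT false
flags on n = 20 samples, second-level FDR on 20+20 subjects × 8 channels.
Parameter recovery uses 100–200 simulated sessions on a reduced 6-channel
montage (the three LDLPFC channels plus three others) and 20 EV samples of
50,000 events per planted fraction. The end-to-end directional check runs
50 cohorts of 12+12 subjects on an 8-channel montage with 5,000-event EV
tables for feature selection, and 10 cohorts of 17+17 — the classification
sample size of the motivating design — for repeated-split accuracy. These
sizes are the package's own choices for routine verification; all of them
scale up through `SimConfig` without code changes.

# Known limitations

* AR-prewhitened OLS, not AR-IRLS; no robust reweighting of motion-heavy
  epochs beyond the explicit spike/step correction.
* No short-separation regression or superficial-signal nuisance modeling.
* SNIRF/HDF5 ingestion is not included; recordings travel as wide CSV
  (time in seconds first, then `<channel>_<wavelength>` columns).
* The montage's channel labels beyond the three LDLPFC pairs are a
  documented convention (a 4×8 frontal checkerboard of 16 sources and 16
  detectors), not a published coordinate list; analyses depend only on
  labels and the LDLPFC set.
* Graph analysis is undirected and unsigned; negative correlations are
  discarded by design rather than analyzed.
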