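---
title: "Methods: synthetic EEG emotion classification and behavioral statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG emotion classification and behavioral statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models, parameters, and
design choices. Every empirical statement here is one the test suite or
`scripts/acceptance.R` computes; nothing is quoted from elsewhere.

## The pipeline in one paragraph

Three emotional states (neutral, fear, anger) are represented by
14-channel, 128-Hz synthetic EEG with state-specific spectral and
complexity signatures. Each recording is baseline-corrected, band-pass
filtered (0.5–50 Hz, zero-phase windowed-sinc FIR), notch-filtered
(50 Hz), cut into non-overlapping 1-s epochs, and cleaned by threshold
rejection. Each epoch contributes a four-dimensional feature vector —
sample entropy and band power on channels T7 and T8 — per analysis band
(delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma 31–47 Hz). A KNN
classifier is scored per band with stratified cross-validation. In
parallel, a behavioral simulator produces participant × emotion trial
tables analysed by one-way and 3×2 factorial ANOVA, simple effects, and
multiple regression with VIF.

## The synthetic EEG generator

Each channel is built as
`x = (1 − c) · structured + c · white`, both terms unit-RMS, where
`structured` is a sum of per-band noise components (white noise whose FFT
is masked to the half-open band `[f_lo, f_hi)`, weighted by the profile's
band amplitudes) and `c` is the profile's *complexity*. FFT masking was
chosen over FIR filtering for the generator because it is exactly
band-limited, cheap, and leaves no filter transients; the conditioning
chain still uses real filters, so the pipeline never benefits from this
shortcut. Raising `c` injects broadband irregularity, which raises sample
entropy; the suite checks this as a majority-over-seeds trend.

The per-channel scale is fixed at 18 µV RMS. With approximately Gaussian
amplitudes this puts typical peaks near ±50–70 µV — ordinary scalp-EEG
magnitudes — while staying clear of the 100 µV rejection threshold, so
that on clean data the artifact stage rejects (essentially) nothing and
every rejection in a test is attributable to an injected artifact.

The three shipped profiles differ in both band weights and complexity
(neutral: alpha-dominant, c = 0.15; fear: beta/gamma-weighted, c = 0.60;
anger: delta/theta-weighted, c = 0.35). They are config-visible constants
chosen to give the classes distinct, learnable signatures; no
quantitative description of real per-state EEG differences was available
to calibrate against, so the profiles are explicitly illustrative, not
physiological claims.

Injected artifacts are (a) blinks: Gaussian-shaped transients
(SD 0.06 s, i.e. ~0.3 s visible width) weighted toward prefrontal
channels, `round(rate × minutes)` of them at uniformly drawn times that
are returned so rejection can be audited against the schedule; and
(b) mains interference: a pure sinusoid on all channels.

## Conditioning

* **Band-pass** — Hamming windowed-sinc FIR, length
  `⌈3.3 · fs / transition_width⌉` taps (845 at the 0.5 Hz default),
  applied forward–backward (`signal::filtfilt`), so phase is zero and
  epoch timing is preserved; the magnitude response is squared, giving
  ~106 dB stop-band attenuation at DC. Zero-phase application was chosen
  because nothing in the study design constrains phase handling and it
  keeps epochs aligned with the raw signal.
* **Notch** — second-order Butterworth band-stop (default 50 ± 1 Hz),
  also forward–backward. Measured in the tests: ≥ 20 dB suppression of a
  pure 50 Hz line and < 1 dB change one bandwidth away. The default is
  50 Hz mains, configurable to 60.
* **Epoching** — non-overlapping 1-s windows, trailing partial window
  dropped (constant epoch shape beats padding artifacts), labels
  inherited from the recording.
* **Rejection** — an epoch is dropped if any sample exceeds the
  amplitude limit (default 100 µV) or, optionally, any first difference
  exceeds a gradient limit. This threshold rule replaces component-based
  ocular cleanup: with synthetic data the artifact schedule is known, so
  thresholding provably removes exactly the contaminated epochs, which is
  what the tests verify. Component methods would add an external
  dependency without adding testable behavior here.

## Features

**Sample entropy.** `SampEn = −ln(A/B)` with Chebyshev distance,
self-matches excluded, unordered pairs counted once, and both `A`
(length m+1) and `B` (length m) counted over the first `N − m`
templates. Defaults `m = 2`, `r = 0.2 · SD` are the standard practice for
short biosignal windows; with `N = 128` (1-s epochs) larger `m` makes
matches too scarce. Conventions at the edges: a constant series returns 0
(all templates match, A = B); no m-matches at all is an error ("undefined
entropy"); m-matches but no (m+1)-matches returns `Inf` with a warning,
and the feature-matrix builder treats non-finite features as an error.
The implementation is checked against an exhaustive O(N²)
template-counting oracle on 200 random series to 1e-10. One deliberate
deviation from a folk invariant: the finite-sample estimator is *not*
strictly monotone in `r` (both match counts shrink together), so the
suite asserts the true property — tightening `r` raises SampEn on
average — rather than per-series monotonicity.

**Band power.** The raw single-window periodogram, one-sided and scaled
so that `sum(power) · Δf` equals the time-domain mean square (verified
via Parseval to 1e-6); band power integrates the bins in the half-open
interval `[f_lo, f_hi)`, so 4 Hz belongs to theta, not delta, and the
conventional 30–31 Hz beta/gamma gap is preserved as printed. Welch
averaging (50 % overlap, Hamming) is available behind a flag but the
default is the raw periodogram, matching the plain `|X̂(f)|²/T`
definition. SampEn is band-independent, so the band-comparison loop
computes it once and reuses it.

Two open readings were settled as follows: entropy is computed *per
epoch per channel* (required to give each of the 216 epochs a feature
vector), and PSD features are *per-band scalars* (matching per-band
classifiers and a 2-D-per-channel feature layout: SampEn + band power on
each of T7, T8 → 4 columns).

## Classification

Euclidean KNN on z-scored features (scaling fit on training folds only),
`k = 5` by default — no optimal `k` is on record for the emulated design, so
the default is a package decision, and `select_k()` provides the usual
empirical selection step as a cross-validated grid search with ties
resolved to the smallest `k`. Vote ties are broken by the class of the
single nearest neighbor. Per-class scores are neighbor-vote fractions,
which feed a one-vs-rest threshold-sweep ROC with trapezoidal AUC.
Evaluation is stratified 5-fold cross-validation at epoch level; because
epochs cut from one continuous recording are correlated, epoch-level CV
is optimistic about subject-level generalization — with one recording
per state here, the alternative (leave-one-recording-out) would conflate
class and recording, so the epoch-level design is the honest option for
this synthetic setting and its accuracies should be read as internal
consistency numbers, not human-subject claims.

## The behavioral generator and statistics

Each table is `n` participants (default 22) × 3 emotions.
Psychological-capital scores are uniform on the observed 3.29–4.75 range
with exactly half the participants on each side of the 4.0
dichotomization threshold, giving the balanced 3×2 layout the classical
ANOVA decomposition requires. Cell means are
`emotion_mean ± (main shift + moderation)/2`, so marginal emotion means
are exact. RA and RS get Gaussian noise (clipped to [0, 1] and [1, 5] as
a safety net); response times are lognormal with the stated mean and SD,
which keeps them positive and right-skewed as real RTs are.

Residual SDs (RA 0.07, RT1 1500 ms, RS 0.30, RT2 1200 ms) were fixed
once so that the bounded scales stay ≳ 4σ from their limits: the suite
verifies that clipping never fires for the shipped preset across 100
seeds, which keeps the generated means unbiased. The structured preset
encodes the qualitative pattern the package emulates — RA ordered
fear > anger > neutral (means 0.5486 / 0.6522 / 0.5955 for
neutral/fear/anger), RT1 and RT2 shortest under fear, RS highest under
fear and lowest under anger — with moderation directions taken from the
reported cell means and covariate slopes keeping the reported
coefficients' signs at one-fifth magnitude (taken literally, those
coefficients push RT population means negative over the covariate
ranges; they are small-sample estimates with VIFs up to ~2). The preset
is ordinal-pattern emulation, not a fit.

The ANOVA stages use a fully between-subjects decomposition even though
each participant appears under all three emotions, mirroring the
randomized-factorial treatment such designs are commonly given; a
repeated-measures treatment would need a different error model and is
out of scope. η² is reported in both classical (`SS/SS_total`) and
partial (`SS/(SS + SS_error)`) forms since printed tables of this kind
rarely say which they use. Simple effects default to the pooled
full-model mean-square error (`F = MS_focal(level)/MSW`, error df from
the full model) with a within-level option that reproduces the
restricted one-way ANOVA; post hocs are pooled-SD pairwise t tests with
Bonferroni correction over the three emotion contrasts, reported with
direction. `anova_from_summary()` audits printed mean ± SD × n tables by
expanding each cell into a surrogate sample with exactly those moments —
valid because F depends on the data only through them — and is checked
to round-trip the raw-data F. VIF is `1/(1 − R²_j)` from regressing each
predictor on the others.

Calibration, not table-matching, is the target for inference: under the
null generator the factorial emotion test rejects at close to the
nominal 5 % (500 replicates, KS-uniform p-values), and an injected
+0.10 RA shift is recovered without bias over 200 replicates at n = 22.
No raw data exist for the emulated design, and several of its published
summary statistics are mutually inconsistent, so no published inferential
statistic is asserted anywhere in this package; the one exactly
reproducible quantity — the delta-band confusion accounting
(208/162/142 of 216 → TP 96.3 %/75 %/65.7 %, overall 79.0 %) — is.

## Problem sizes and numerical conventions

The shipped study scale is 216 s per state at 128 Hz (216 one-second
epochs per class, 648 pooled), 22 × 3 behavioral rows, 500-replicate
null calibration, and 200-replicate recovery runs; the full test suite
and the acceptance script each complete in well under a minute of
compute on a single core at these sizes. Other conventions: half-open
frequency intervals everywhere; stable `order()`-based neighbor and
threshold ties; zero-variance feature columns are left unscaled rather
than producing NaNs; the EDF writer rounds each signal's physical range
outward to two decimals so the 8-character header fields carry the
calibration exactly (round-trip error is then pure 16-bit quantization).
All randomness flows through explicit seeds; library calls save and
restore the caller's RNG state.

## Limitations

The EEG generator makes no claim to biophysical realism (no 1/f
background, no topographic source structure, no nonstationarity), so
classification accuracies on it say nothing about accuracies on human
data — they establish that the pipeline separates classes that are
separable and not ones that are not (label-shuffled accuracy stays at
chance). The behavioral generator likewise emulates a factor structure,
not a population. EDF support covers the minimal 16-bit, single-rate,
14-channel case the pipeline itself writes.
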