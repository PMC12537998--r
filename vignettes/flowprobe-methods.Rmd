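---
title: "Probing attentional resources under workload: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing attentional resources under workload: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowprobe)
```

## The scientific problem

In a dual-task paradigm a participant plays a demanding primary task (a
game whose difficulty induces mental underload, a flow state, or overload)
while rare target tones — oddballs at 20% probability, 2–2.4 s jittered
inter-stimulus intervals — are silently counted as a secondary task. The
P300 evoked by the oddball indexes the attentional resources left over for
the secondary task: it is large under underload, attenuated under overload,
and smallest during flow, where immersion shields attention from the
distractor. `flowprobe` implements the complete analysis chain for such
studies — preprocessing with a surface-Laplacian current source density
(CSD) transform, mass-univariate spatiotemporal cluster permutation
statistics, time-resolved multivariate decoding with bootstrap inference
and Haufe pattern interpretation, and the behavioral statistics — together
with a synthetic EEG generator that makes every stage testable without any
recordings.

## The synthetic generator

`simulation_config()` fixes the generative model; `simulate_epochs()`,
`simulate_continuous_session()` and `simulate_behavior()` draw from it.

**What it emulates.**

* 32-channel 10–20 cap (FCz reference, Fpz ground) on an idealized unit
  sphere; 250 Hz sampling; epochs on the half-open window [−0.2 s, 1.0 s)
  (300 samples).
* An event stream with *exactly* `round(0.2 n)` oddballs per `n` events
  (a permuted fixed multiset, not Bernoulli draws — the fixed proportion
  makes counts exactly testable) and i.i.d. uniform ISIs on [2.0, 2.4] s.
* A single-trial oddball response: a Gaussian P300 bump (peak 0.45 s,
  SD 0.10 s) on a centroparietal topography (peak at CP1/CP2/Pz), scaled
  by the condition amplitude — defaults 8 µV (underload), 4 µV (overload),
  1 µV (flow) — and a per-subject log-normal gain (SD 0.1); plus a
  condition-independent auditory N1 (−4 µV, 100 ms) / P2 (+3 µV, 200 ms)
  complex on a frontocentral topography. Standards carry only the N1/P2.
  The P300 SD of 0.10 s makes the between-condition difference emerge only
  after roughly 250 ms and persist through the late window, as a P3b does;
  a narrower bump would produce implausibly brief decodable windows.
* Sensor noise: 1/f ("pink") noise with spectral exponent 1.0 and
  per-channel SD 8 µV, composed of (a) a spatially *smooth* background —
  channel noise mixed through a gaussian kernel in great-circle angle
  (σ = 0.9 rad, 90% of the variance) emulating volume-conducted brain
  noise, (b) a 10% spatially white electrode-noise floor, and (c) a
  shared low-rank (rank 3) component. The spatial smoothness matters: a
  surface Laplacian is a spatial high-pass, so spatially *white* noise of
  equal power would dominate the CSD-domain signal in a way real
  volume-conducted EEG does not, and the correlated sensors are precisely
  what makes Ledoit–Wolf shrinkage LDA worthwhile.
* Continuous sessions embed the event-locked templates in continuous
  noise and add stereotyped artifacts: ~300 ms squared-sine blinks with a
  frontal (Fp1/Fp2) topography at 12/min mirrored in an EOG trace, and
  sharp biphasic cardiac spikes on a broad shallow anterior–posterior
  gradient at 70/min mirrored in an ECG trace.
* Behavioral tables (relative game score, NASA-TLX, Flow Short Scale,
  oddball count error) as Gaussian cells around per-condition means with a
  per-subject random intercept; the ergonomic-position factor is
  generatively null, so the two-factor analysis has a true-null factor to
  calibrate against. The default means encode the inverted-U performance
  profile (score highest during flow, lowest under overload), higher
  subjective flow during the flow condition, monotone workload ratings,
  and a larger counting error during flow.

**What it does not emulate.** No individual head geometry (electrode
positions are ideal-sphere angles), no oscillatory (alpha/beta) structure
or event-related desynchronization, no latency jitter or habituation of
the P300 across trials, no muscle or line-noise artifacts, no
non-stationarity across a session, and between-subject variability only as
a scalar amplitude gain. Passing tests therefore certify the *machinery* —
estimator correctness, calibration of the permutation and bootstrap
inference, qualitative parameter recovery — not performance on real
recordings.

All randomness flows from one root seed through `derive_seed()` offsets
per stage, subject and condition, so any sub-computation is independently
reproducible.

## Preprocessing chain

The chain runs in the fixed order detrend → band-pass → segment → reject
→ (component hook) → baseline → per-epoch interpolation → CSD
(`preprocess_session()`), with each stage recorded in the epoch object's
`history`.

* **Band-pass**: order-4 Butterworth, 0.2–20 Hz, applied forward–backward
  (`signal::filtfilt`). Zero-phase filtering was chosen because a causal
  pass would delay ERP latencies; the effective magnitude response is the
  squared single-pass response, which the tests check against the analytic
  prewarped Butterworth formula.
* **Rejection**: channels by robust z (median/MAD) of pooled log-variance
  at 5 SD; epochs by robust z of the maximum peak-to-peak amplitude or the
  mean log-variance at 3 SD. Robust centring makes a single gross outlier
  flaggable even in small trial counts, and z-scores make all decisions
  amplitude-scale-free. With zero spread nothing is flagged.
* **Component metrics** (FASTER family): maximal |Pearson r| against
  EOG/ECG traces, excess kurtosis, rescaled-range Hurst exponent (with the
  Anis–Lloyd small-sample correction; white noise ≈ 0.5), high/low-band
  log power gradient, and median absolute first difference; a component is
  flagged when any metric's robust z across components exceeds 3. The ICA
  decomposition itself is a pluggable hook (`ica` argument): any provider
  of an unmixing/mixing pair can be used, and flagged components are
  zeroed before back-projection. Only the metrics are in scope here.
* **Baseline**: subtraction of the per-trial, per-channel mean over
  [−0.2, 0) s (half-open, excluding the onset sample); idempotent by
  construction.
* **Epoch window**: the analysis epoch is 1.2 s total — a 200 ms
  pre-stimulus baseline plus the 1 s post-onset analysis interval — on
  half-open sample windows (`round((onset+tmin)·fs)` inclusive to
  `round((onset+tmax)·fs)` exclusive), giving exactly 300 samples at
  250 Hz and 120 at 100 Hz.

## Sensor geometry and the CSD transform

Spherical splines (stiffness `m`, kernel
`g(x) = (1/4π) Σ_n (2n+1)/(n(n+1))^m P_n(x)`) interpolate bad channels
and yield the surface Laplacian analytically: each Legendre term is a
degree-*n* surface harmonic, so the Laplacian multiplies it by −n(n+1),
giving the companion kernel `h`. Defaults are m = 4, ridge regularization
λ = 1e−5 on the spline system, 50 Legendre terms with a 1e−10 term
tolerance, and a 0.085 m head radius for µV/m² scaling — common CSD
practice; all are exposed as arguments since the upstream choices are not
universal. The transform is linear, annihilates spatially constant fields
and is invariant to the recording reference; on a degree-1 harmonic it
reproduces the analytic eigenvalue −2 to within the discretization error
of a 32-channel cap (largest at the sparsely covered rim, which is why the
tests compare the *fitted* proportionality constant rather than per-rim
channel values).

Sensor adjacency for clustering links channels within 0.78 rad
great-circle angle, chosen once so the median channel on the 32-channel
layout has 4–6 neighbours and homologous centroparietal pairs (CP1–CP2,
44°) count as neighbours; a spherical Delaunay triangulation (convex-hull
faces, trans-head edges discarded) is available as an alternative.

## Cluster permutation statistics

Pointwise repeated-measures F maps (subject effect partialled out; df
(k−1, (k−1)(n−1))) or paired-t maps are thresholded at the parametric 95th
percentile of the pointwise null by default (configurable), clusters are
connected components over the space–time graph ((c,t)–(c,t±1) and
(c,t)–(c′,t) for adjacent c, c′), and the cluster statistic is the summed
("mass") statistic, signed per polarity for two-sided maps. The null is
the distribution of the maximum |mass| under within-subject relabeling:
condition permutation per subject for F, difference sign-flips per subject
for t, restricted permutation (within levels of the other factor) for
two-factor main effects. Monte-Carlo p is `(1 + #{null ≥ obs})/(1 +
n_perm)` (default 1024 permutations); when the exhaustive sign-flip space
is no larger than `n_perm` all 2^n patterns are enumerated and p is exact.
A 1e−9 comparison tolerance guards floating-point ties at the identity
relabeling. Degenerate zero-variance points clamp to a large finite
statistic rather than ±∞.

## Time-resolved decoding

Epochs are downsampled to 100 Hz (in-package zero-phase polyphase
resampler; see the note below), and per time point a Ledoit–Wolf
shrinkage LDA (`w = Σ*⁻¹(μ₂−μ₁)`, `Σ* = (1−ρ)S + ρ(tr S/p)I`, ρ the
analytic optimal intensity on the pooled within-class scatter with the
maximum-likelihood 1/n convention) is trained and scored under 5-fold
stratified cross-validation repeated 20 times — 100 folds per time point.
Binary contrasts are scored by AUC (Mann–Whitney form, ties counted half);
the three-class problem by one multiclass LDA (per-class discriminants,
argmax prediction) under support-weighted F1. A stratified dummy
classifier — test predictions drawn i.i.d. from the training label
distribution, scored identically, time axis replicated — defines empirical
chance.

Inference bootstraps the fold scores (5000 Monte-Carlo resamples of the
pooled subject × fold score vector per time point; percentile 95% CI), and
a time interval is significant when the decoder's lower CI exceeds the
dummy's upper CI for at least 200 consecutive milliseconds, counted as
`n_points/fs ≥ 0.2` — 20 points at 100 Hz qualify, 19 do not. Decoding is
subject-wise (per-subject CV) with scores pooled across subjects before
the bootstrap; `decode_group()` implements this default and the bootstrap
treats dummy scores symmetrically.

Decoder weights are transformed into activation patterns per fold on the
training data (`A = Σ_X W Σ_ŝ⁻¹`, the Haufe transform; for one
discriminant this is `Cov(x, ŝ)/Var(ŝ)`), averaged across folds and then
subjects. Interpretation is restricted by a univariate spatiotemporal
mask: bootstrap CIs (5000 iterations) of the subject-mean evoked response
per condition, a (channel, time) point being masked in when one
condition's CI is disjoint from both others'. `peak_summary()` extracts
the pattern slice and per-condition evoked CIs in the masked region at the
time of maximal bootstrap-mean performance within the significant
intervals. Because shrinkage biases `Σ*⁻¹` toward the identity, the
estimated pattern is mildly biased toward `Σ_X`'s leading structure at
small trial counts; pattern recovery is therefore assessed on the masked
(informative) sensors, mirroring how masked patterns are interpreted in
practice.

**Resampler note.** `signal::resample()` mis-aligns output for rational
ratios (uncompensated group delay), so the package builds the polyphase
resampler directly: edge-replicate padding, zero-stuffing by p, a
zero-phase FIR low-pass at the tighter Nyquist (`signal::fir1` +
`filtfilt`), then decimation by q, assembled once as a linear operator and
applied to all trials and channels.

## Behavioral statistics

The two-factor within-subject ANOVA (difficulty × ergonomic position)
uses the full sums-of-squares decomposition with each effect tested
against its own subject-interaction error term. The Greenhouse–Geisser ε
of an effect comes from the covariance of its orthonormal contrast scores
(`ε = tr(V)²/(df·tr(V²))`); corrected p-values evaluate F at (ε·df₁,
ε·df₂); effect size is partial η² = SS_eff/(SS_eff+SS_err). Post hoc Tukey
HSD on a within-subject factor uses that factor's own error term (df =
(k−1)(n−1), matching df = 24 at 13 subjects and 3 levels) and base R's
studentized-range distribution. The relative game score is
`p_won/(p_won+p_lost)` (defined as 0.5 when no points were scored, with a
warning) and the secondary-task measure is the signed relative count
error `(counted − true)/true`.

## Numerical choices and degenerate inputs

* Exact oddball counts by permutation, never Bernoulli.
* Zero-variance channels/epochs/components: robust z with MAD → nothing
  flagged when spread is zero; constant components get zero metrics and a
  warning; zero-variance paired differences clamp to ±1e12.
* Spline systems solve the constrained (mean-zero) formulation with λ on
  the diagonal; the constant mode carries no Laplacian.
* All bootstrap/permutation p-values respect their floors
  (`1/(n_perm+1)`, CI levels) and seeds are explicit everywhere.
* Config → report is a pure function: `run_pipeline()` called twice with
  the same config (including seed) returns identical reports.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the pipeline at desk
scale, chosen as the smallest sizes at which the qualitative contracts are
stable: 6 simulated subjects, 100 oddball trials per condition, 5-fold CV
with 3–5 repeats for the group decoding runs, 1000–2000 bootstrap
replicates, and 200 simulated null datasets for the type-I calibration of
the cluster test (with exhaustive 2⁶ sign-flip enumeration). The
generator's *defaults* remain at the study scale (13 subjects, 100 trials,
100 folds, 5000 replicates). The hardest contrast (flow vs overload, a
3 µV generative difference) often yields no or only a brief significant
interval at desk scale — the same qualitative behaviour as the narrow
window reported for that contrast at full scale — so the contrast-ordering
check uses mean window scores rather than interval lengths.

## Known limitations

* The generator's noise is stationary and Gaussian; robustness claims
  against real artifacts rest only on the stereotyped blink/ECG models.
* The ICA hook computes metrics and zeroes components; no unmixing
  algorithm ships with the package.
* Bootstrap CIs over CV folds treat folds as exchangeable although
  repeated CV reuses trials across folds; this mirrors the analysis
  convention the package implements, and the 200 ms duration criterion is
  the guard against the resulting optimism.
* The spherical-spline CSD is an idealized-sphere estimate; no individual
  head models.
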