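# flowprobe

Analysis toolkit for dual-task auditory oddball EEG studies of mental
workload and flow. In these experiments a participant plays a primary game
task whose difficulty induces mental **underload**, a **flow** state, or
**overload**, while silently counting rare target tones (20% oddballs,
2–2.4 s jittered ISIs). The P300 evoked by the oddball indexes the
attentional resources left for the secondary task: largest under
underload, attenuated under overload, smallest during flow — the
"attentional shielding" signature.

`flowprobe` implements the full chain on which such claims rest:

* **Synthetic generator** — 32-channel 10–20 EEG at 250 Hz with
  condition-dependent centroparietal P300 amplitudes, 1/f spatially
  correlated noise, blink/ECG artifacts, exact-count oddball schedules,
  and behavioral tables; every stage is testable without recordings.
* **Preprocessing** — detrend; zero-phase order-4 Butterworth 0.2–20 Hz;
  half-open epoching (−0.2 to 1.0 s); 5 SD / 3 SD robust channel/epoch
  rejection; FASTER-style component metrics (EOG/ECG correlation,
  kurtosis, Hurst exponent, power gradient, median gradient) with a
  pluggable ICA hook; 200 ms baseline; per-epoch spherical-spline
  interpolation; surface-Laplacian CSD (reference-free, µV/m²).
* **Cluster statistics** — pointwise repeated-measures F / paired-t maps,
  spatiotemporal cluster formation over a sensor adjacency graph,
  max-cluster-mass permutation null (within-subject relabeling or
  sign-flips; exhaustive when feasible), Maris–Oostenveld style p-values.
* **Decoding** — per-time-point Ledoit–Wolf shrinkage LDA
  (`w = Σ*⁻¹(μ₂−μ₁)`, `Σ* = (1−ρ)S + ρ(tr S/p)I`), 5×20 stratified CV
  (100 folds per time point), AUC / weighted-F1 scoring, stratified dummy
  baseline, 5000-iteration bootstrap CIs, the ≥200 ms significance
  criterion, Haufe activation patterns (`A = Σ_X W Σ_ŝ⁻¹`) with a
  univariate bootstrap-CI spatiotemporal mask, and peak summaries.
* **Behavioral statistics** — relative game score, oddball count error,
  two-factor within-subject ANOVA with Greenhouse–Geisser correction and
  partial η², Tukey HSD on the within-subject error term.
* **Pipeline** — `run_pipeline()` sequences the stages from one nested,
  schema-validated, fully seeded configuration and emits a JSON report.

## Worked example

```r
library(flowprobe)

mon <- build_standard_montage()          # 32-channel 10-20 cap
cfg <- simulation_config(n_subjects = 4, n_trials_per_condition = 60,
                         seed = 7)

# simulate + preprocess one subject, all three workload conditions
study <- lapply(1:4, function(s) {
  eps <- lapply(c("underload", "flow", "overload"), function(cond)
    downsample_epochs(surface_laplacian_csd(
      baseline_correct(simulate_epochs(cfg, cond, subject = s)), mon), 100))
  setNames(eps, c("underload", "flow", "overload"))
})

res <- decode_group(study, c("underload", "flow"),
                    n_repeats = 5, n_boot = 2000, seed = 7)
res$intervals
#>      start end
#> [1,]  0.28 0.6
res$summary$peak_score
#> [1] 0.8233686
res$summary$peak_time
#> [1] 0.44
```

The decoder separates underload from flow from about 280 ms after tone
onset (the window in which the P300 difference is expressed), peaking at
AUC ≈ 0.82 around 440 ms — the single-trial signature of the generative
amplitude difference (8 µV vs 1 µV at centroparietal sensors under 8 µV
1/f noise). The group-level cluster statistic on the same data:

```r
ev <- array(0, c(4, 3, 32, 120))
for (s in 1:4) for (k in 1:3) ev[s, k, , ] <- evoked(study[[s]][[k]])
adj <- compute_adjacency(mon)
cl <- permutation_cluster_test(ev, design = "F", n_perm = 500,
                               adjacency = adj, seed = 7)
min(cl$p_values)
#> [1] 0.003992016
```

the strongest spatiotemporal cluster — centroparietal sensors in the
P300 window — survives the max-cluster-mass permutation null at
p ≈ 0.004.

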