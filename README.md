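# drivernet

Recognition of distracted driving states from multichannel EEG functional
brain networks.

Driver distraction comes in two flavors — *cognitive* ("mind off road",
e.g. mental arithmetic) and *visual* ("eye off road", e.g. watching a
phone) — and both reorganize the cortical functional network measured by
EEG: theta- and beta-band inter-channel coupling rises under distraction
while alpha coupling drops slightly. `drivernet` implements the full
analysis chain that turns raw multichannel EEG into a ternary state call
(normal / cognitive / visual), plus a seeded generator of coupled
narrowband cohorts so the whole chain is testable end-to-end without access
to proprietary recordings.

## The method

1. **Preprocessing.** Recordings are resampled (default 512 Hz), bandpass
   filtered with a zero-phase FIR design (0.5–40 Hz), cut into labeled
   epochs (default 10 s), and decomposed into δ (0.5–4 Hz), θ (4–8 Hz),
   α (8–13 Hz) and β (13–30 Hz) band signals by a db4 wavelet packet tree
   (level 7; an FIR filter bank is available as an alternative).
2. **Connectivity.** For every band, three estimators fill a symmetric
   channels × channels matrix `C` with entries in [0, 1]:
   - *Synchronization likelihood* (SL): embedding-based generalized
     synchronization. With per-time critical distances set so that a
     fraction `p_ref` of embedded states within a Theiler-corrected window
     recur, `SL_xy` is the likelihood that x-recurrences are
     simultaneously y-recurrences (≈ `p_ref` for independent signals, 1
     for identical ones).
   - *Phase locking value* (PLV): `PLV_xy = |⟨exp(i(φ_x(t) − φ_y(t)))⟩_t|`
     with instantaneous phases from the analytic signal; amplitude-blind.
   - *Magnitude-squared coherence* (COH): Welch-averaged
     `|S_xy|² / (S_xx S_yy)`, averaged over the in-band frequency bins.
3. **Topology.** Each matrix is binarized over a sparsity sweep (13–47% in
   1% steps; admission rules: mean degree > 2·log₁₀(n) and small-world
   σ > 1.1 against degree-preserving nulls). Per graph the package computes
   characteristic path length `L_g`, clustering coefficient `C_g`, global
   efficiency `E_g` and local efficiency `E_l`; each curve is aggregated as
   its area under the sparsity curve divided by the grid width.
4. **Recognition.** The 60 features (3 estimators × 4 bands × {V, C_g,
   L_g, E_g, E_l}, where V is mean connection strength) feed KNN, random
   forest, gradient boosting, or an RBF-kernel SVM, evaluated with a
   stratified 90/10 reserve plus 10-fold cross-validation and
   fold-internal standardization; tree ensembles report normalized
   feature-importance shares per network and band.
5. **Statistics.** Band-wise one-way ANOVA of any feature across the three
   states with explicit Bonferroni families, and top-2% connectivity
   difference maps between states.

## Worked example

```r
library(drivernet)

# a small synthetic cohort: 2 subjects x 3 states x 5 epochs, 16 channels
cs <- cohort_spec(n_subjects = 2, epochs_per_state = 5,
                  n_channels = 16, seed = 11)
cohort <- generate_cohort(cs)

tab <- build_feature_table(cohort)     # 30 epochs x 60 features
aggregate(plv_theta_V ~ label, tab, mean)
#>       label plv_theta_V
#> 1 cognitive   0.1370587
#> 2    normal   0.1133942
#> 3    visual   0.1727165

rep <- train_evaluate(tab, task = "ternary", classifier = "gboost", seed = 5)
rep
#> <recognition_report> ternary / gboost (split by epoch)
#>   CV accuracy (9 folds): 0.926
#>   held-out: Acc 1.000  P 1.000  Re 1.000  F1 1.000
```

The theta-band PLV strength rises from normal (0.113) through cognitive
(0.137) to visual distraction (0.173) — the coupling signature the
generator embeds and the ANOVA stage tests — and even this 30-epoch toy
cohort supports ~93% cross-validated ternary accuracy; at the package's
validation scale (6 subjects × 10 epochs per state) gradient boosting
reaches ~0.98 ternary and ~0.99 binary CV accuracy. A single-config
end-to-end run with full artifact output
(`matrices/`, `features.tsv`, `reports/`, `contrasts/`, `provenance.json`):

```r
run_pipeline(default_pipeline_config(), "out/")
```

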