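---
title: "Brain-network recognition of driving states: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-network recognition of driving states: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drivernet)
```

This vignette is the package's own account of the science it implements:
the signal model, the three synchronization estimators, the graph
pipeline, the evaluation protocol, and every place where the design was
genuinely open and a choice had to be made.

## The problem

Cognitive distraction ("mind off road") and visual distraction ("eye off
road") change how cortical regions synchronize. Multichannel EEG captures
this as band-specific changes in pairwise coupling: under distraction,
theta- and beta-band coupling strengthens while alpha coupling weakens
slightly. The package estimates that coupling, reduces it to global
network topology, and classifies the driver's state from the resulting
feature vector.

## What the synthetic generator emulates — and what it does not

Real study recordings behind this line of work are not publicly
deposited, so the package carries a generator whose cohorts exercise every
downstream stage against a known ground truth.

Per band $b$, coupled channels share a unit-RMS narrowband stochastic
oscillator $s_b(t)$ (complex-Gaussian Fourier coefficients restricted to
the band, so spectral support is exact), mixed against an independent
component $e_{i,b}(t)$:

$$x_{i,b}(t) = a_b\,[\kappa_b\, s_b(t) + (1 - \kappa_b)\, e_{i,b}(t)].$$

$\kappa_b \in [0,1]$ is a graded coupling dial: at 0 the channels are
independent, at 1 identical within the band, and PLV/COH increase
monotonically in between. Because linear mixing under-exercises the
generalized-synchronization sensitivity of SL, a state's spec may
additionally superimpose unidirectionally coupled Hénon-map trajectories
(driver $x_{n+1} = 1.4 - x_n^2 + 0.3 x_{n-1}$; the response's quadratic
term mixes in the driver with weight mapped from the mean $\kappa$) on
consecutive coupled channel pairs. White Gaussian noise (default SD 0.5
against unit-RMS band oscillators) is added last.

The default state conventions mirror the qualitative signature the
analysis targets, with absolute levels chosen once as synthetic
conventions (they are **not** measured values):

| state     | δ    | θ    | α    | β    | nonlinear |
|-----------|------|------|------|------|-----------|
| normal    | 0.25 | 0.20 | 0.40 | 0.20 | no        |
| cognitive | 0.30 | 0.40 | 0.34 | 0.50 | yes       |
| visual    | 0.28 | 0.55 | 0.32 | 0.35 | no        |

θ and β are elevated under distraction and α slightly depressed; visual
distraction peaks in θ, cognitive in β and carries the nonlinear
component. Study-scale structural constants are kept as defaults: 63
channels, 512 Hz, 10-s epochs. Per-epoch seeds derive from a stable hash
of (master seed, subject, state, epoch), so cohorts regenerate
bit-identically.

The generator does **not** emulate eye-blink/EMG artifacts, volume
conduction, 10-10 spatial covariance beyond pairwise coupling, or
subject-level random effects. Passing tests therefore demonstrate that the
pipeline recovers planted coupling structure — not that it is robust to
real-world artifacts, which are assumed cleaned upstream.

## Preprocessing

* **Resampling** is polyphase rational-rate resampling with anti-alias
  filtering (`signal::resample`), e.g. 1000 → 512 Hz.
* **Bandpass**: an order-1536 Hamming-window FIR (0.5–40 Hz) applied
  forward–backward, i.e. exactly zero phase with the squared design
  magnitude. The two-pass response suppresses 0.1 Hz and 60 Hz by more
  than 40 dB. Application happens in the frequency domain (circular),
  which matches `filtfilt` away from epoch edges at a fraction of the
  cost; epochs are baseline-corrected by per-channel mean subtraction
  (no parameters are attached to "baseline correction" beyond this).
* **Band decomposition** offers two methods because the underlying
  wavelet choice is not canonical:
  * `wpt` (default): full db4 wavelet packet tree, depth 7 at 512 Hz
    (terminal bandwidth 2 Hz), periodic boundary, terminal nodes mapped to
    frequency order by the standard sequency rule. A band's signal is the
    inverse transform of the nodes whose nominal support overlaps the band
    most (ties to the lower band), which makes band supports disjoint
    under the half-open `[lo, hi)` edge convention; the 12–14 Hz node goes
    to alpha — a documented approximation of the 13 Hz edge. The
    implementation is verified by perfect reconstruction (~1e-11) and by
    FFT oracles (tones land in their band with ≥ 80% energy).
  * `fir`: per-band zero-phase FIR filters, sharper band edges, usable for
    epoch lengths not divisible by $2^{\text{level}}$.

## Connectivity estimators

All three return symmetric matrices, zero diagonal, entries in $[0,1]$;
only the upper triangle is computed and mirrored so thresholding can never
select self-edges.

**Synchronization likelihood.** Channels are time-delay embedded
(dimension $m = 10$, lag $l = 10$ samples). For a reference time $i$,
candidate recurrences are embedded states $j$ with
$w_1 < |i - j| \le w_2$: the Theiler window $w_1 = 2l(m-1)$ removes
autocorrelation-driven false recurrences, and the outer window
$w_2 = w_1 + \mathrm{round}(n_\mathrm{recur}/p_\mathrm{ref})$ is sized so
about $n_\mathrm{recur} = 10$ recurrences per side fall inside at
reference probability $p_\mathrm{ref} = 0.05$. The critical distance at
$(channel, i)$ is found by exact rank selection (Euclidean metric) so that
exactly $\lceil p_\mathrm{ref}\, n_\mathrm{cand}\rceil$ candidates recur;
$SL_{xy}$ averages, over reference times, the fraction of $x$-recurrences
that are simultaneously $y$-recurrences. Independent signals score
$\approx p_\mathrm{ref}$ (the estimator's floor), identical signals score
1. Because reported group means in this literature (~0.08–0.13) are
consistent with raw values, the package reports raw SL by default and
offers $(SL - p_\mathrm{ref})/(1 - p_\mathrm{ref})$ as an opt-in rescale.
Reference times are strided (default every 8 samples): SL is an average
over reference points, and ~600 points per 10-s epoch estimate it to
~1e-3 while setting the constant factor of the $O(n_\mathrm{ref}\,
n_\mathrm{cand}\, m)$ per-channel cost. None of $m, l, w_1, w_2,
p_\mathrm{ref}$ are canonical in the application literature; all are
config-exposed.

**Phase locking value.** The phase comes from the analytic signal (FFT
method) of the already band-limited channel — no second narrowband filter.
$PLV = |\langle e^{i\Delta\phi}\rangle_t|$ is amplitude-invariant by
construction; constant channels have undefined phase and their entries are
set to 0 with a message. For independent phases the expected value is the
Rayleigh mean $\sqrt{\pi}/(2\sqrt{N})$, which the tests verify.

**Coherence.** Welch-averaged modified periodograms: Hann taper, 2-s
segments, 50% overlap at 512 Hz → 0.5 Hz resolution; the band value is the
mean of $|S_{xy}|^2/(S_{xx}S_{yy})$ over bins whose center lies in
$[lo, hi)$. A single segment gives identically 1 and is rejected; with $L$
independent segments the no-coupling bias is $\approx 1/L$, which the
tests verify against a Monte-Carlo oracle.

## Network topology

Thresholding retains the `round(s · n(n−1)/2)` strongest edges at sparsity
$s$; ties break deterministically by descending weight then ascending
(row, column), so results are platform-stable. The sweep runs 13–47% in 1%
steps (35 points). Two admission diagnostics flag (never drop) grid
points: mean degree $> 2\log_{10} n$ — base 10 because the natural log
would already exclude the grid's own lower bound at $n = 63$ — and
small-world $\sigma > 1.1$, with
$\sigma = (C_g/C_\mathrm{rand})/(L_g/L_\mathrm{rand})$ against 20
Maslov–Sneppen degree-preserving rewirings (10 swap attempts per edge,
seeded). $\sigma$ is computed per grid point.

Metrics (BFS-based, in C++): $L_g$ averages shortest-path lengths over
*reachable* ordered pairs, with the unreachable fraction reported — this
avoids infinities at low sparsity while leaving $E_g$, which counts
unreachable pairs as 0, faithful to its definition. $C_g$ is the
arithmetic mean of local clustering with degree-<2 nodes contributing 0;
$E_l$ is the mean global efficiency of neighbor-induced subgraphs
(< 2 neighbors → 0). Each feature's sparsity curve is aggregated as the
trapezoidal area under the curve divided by the grid width, keeping the
scalar on the feature's own scale. All four metrics are held to 1e-10
agreement with independent brute-force oracles (exhaustive Floyd–Warshall
relaxation, triangle enumeration) on hundreds of random graphs.

## Recognition protocol

The feature vector is 3 estimators × 4 bands × {V, C~g~, L~g~, E~g~,
E~l~} = 60 named columns (`estimator_band_feature`). The stated protocol
"10-fold cross-validation, reserving 10% for testing" is ambiguous between
nested evaluation and CV-as-test; the package implements both readings at
once: an outer stratified 90/10 split, 10-fold stratified CV on the
development 90% (fold accuracies and their mean), and held-out metrics
(confusion matrix, accuracy, macro precision/recall/F1, one-vs-rest ROC
AUC) on the reserved 10%. Standardization parameters come from training
data only, inside every fold — verified by a permutation test driving
accuracy to chance. Splits can be per-epoch or grouped by subject (all
epochs of a subject on one side) to avoid identity leakage; per-epoch is
the default since the original protocol's unit is unstated.

Classifier choices: "moderate" KNN is read as $k = 10$ with Euclidean
distance; the SVM uses an RBF (Gaussian) kernel; random forest uses 500
trees; gradient boosting uses depth-3 trees, $\eta = 0.3$, 100 rounds,
and `tree_method = "exact"` — exact midpoint splits matter on small
tabular data, where histogram splits hug class edges and misassign
held-out points lying marginally outside the training range. All
hyperparameters are fixed, documented, and seeded; no search is performed.
Tree ensembles expose normalized importance (gain or Gini decrease) with
shares aggregated per estimator network and per band.

## State contrasts

One-way ANOVA across the three states, per feature and band, on
epoch-level values pooled over subjects (a subject-mean mode is a
one-liner with `aggregate` upstream; pooling is valid for the generator,
which has no subject random effect). The Bonferroni family is always
declared explicitly — by default the number of feature columns tested in
the run — since the original family definition is unstated. Difference
maps subtract state means and retain the $\lceil k\, n(n-1)/2 \rceil$
largest strictly positive changes (default top 2%), with the same
deterministic tie-break as thresholding.

`power_check()` wraps the whole loop in simulation: under identical state
specs it measures the family-wise type-I rate (Bonferroni keeps it at or
below $\alpha$ at any cohort size); under the default effect specs it
measures power of the theta contrast. The package's calibration runs use
2 subjects × 3 epochs/state × 8 channels — small on purpose, since type-I
control is size-free and the planted theta effect is large.

## Numerical and degenerate-input choices

* Epochs too short for the SL embedding are rejected with the required
  length in the message; `duration * fs` must be an integer.
* Zero-power channels: PLV/COH entries 0 with a message; ANOVA on
  all-identical values returns $p = 1$ with a message instead of NaN.
* All randomness flows through explicit integer seeds; generator, sweep
  nulls, classifiers and simulations restore the caller's RNG state.
* Validation problem sizes used by the test suite: 200 random graphs
  (n ≤ 30) for oracle agreement; 50 noise seeds for the SL baseline;
  20 seeds per point on the Hénon and κ grids; recognition cohorts of
  6 subjects × 10 epochs/state × 16 channels over three master seeds; 200
  null and 50 effect simulations for calibration. These are the package's
  documented validation scales.

## Known limitations

* SL cost grows as channels × reference points × window; the 63-channel,
  35-sparsity configuration is the hotspot, which is why reduced-channel
  defaults (16) drive the example pipeline and the full montage sits
  behind a config field.
* The wavelet packet band edges are 2 Hz-granular; the 13 Hz alpha/beta
  boundary is approximated by node assignment (the FIR method is sharper).
* PLV is sensitive to volume conduction; no correction is applied, and no
  directed or lagged estimators are provided.
* Classification numbers on synthetic cohorts say nothing quantitative
  about real EEG; the recoverable signal is planted by construction.
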