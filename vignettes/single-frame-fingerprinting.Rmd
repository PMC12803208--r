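---
title: "Single-frame connectome fingerprinting: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-frame connectome fingerprinting: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(framefp)
```

## The model

`framefp` treats each fMRI volume as a connectivity observation in its own
right. A node's band-passed BOLD series is narrowband, so its analytic
signal (the series plus i times its Hilbert transform) has a well-defined
instantaneous phase θ(i, t). The per-volume phase-coherence matrix

$$\mathrm{dFC}(i, j, t) = \cos\!\big(\theta(i, t) - \theta(j, t)\big)$$

summarizes which nodes are phase-aligned (+1), in quadrature (0) or in
antiphase (−1) at volume t. Writing c = cos θ(·, t) and s = sin θ(·, t),
the matrix equals ccᵀ + ssᵀ: it is symmetric, positive semidefinite, has
unit diagonal (trace N) and rank at most two. Two consequences follow
directly and are enforced as tested invariants rather than observed
empirically:

* the leading eigenvalue satisfies λ₁ ≥ N/2, so the leading eigenvector
  V1(t) always captures at least 50% of the matrix's variance (λ₁/N);
* the rank-1 reconstruction λ₁V1V1ᵀ misses exactly λ₂ = N − λ₁ in
  Frobenius norm.

V1(t) is therefore a faithful N-dimensional signature of the volume, and
the package computes it through the exact rank-2 reduction (a 2×2
eigenproblem in the span of c and s, O(N) per volume) rather than a dense
eigendecomposition; the two routes are cross-checked in the test suite to
10⁻¹⁰.

Identification follows the target/database protocol. Volumes are compared
by the absolute Pearson correlation of their leading eigenvectors —
absolute, because V1 and −V1 yield the same outer product, so r = −1 means
identical coherence patterns. Each target volume predicts the label
(subject identity, or task) of its best database match; a target scan
predicts the label with the most volume votes. Both accuracy levels are
compared against the chance expectation (volumes per scan divided by the
number of candidate labels) and against a permutation null in which
database scan labels are shuffled as a multiset across scans.

## What the synthetic generator emulates

Real multi-session fMRI cohorts are unavailable to a test suite, so the
package ships a generator whose defaults encode the study conditions the
pipeline is designed for: multiple subjects × sessions × tasks, signals
band-limited to 0.009–0.08 Hz at TR ≈ 2.2 s, a shared group covariance
component, a stable subject-specific component, task and subject×task
components, session noise, and occasional motion spikes.

The latent signal lives on `n_units` acquisition units (default 1000).
For subject s on task k the unit covariance is

$$\Sigma(s,k) = w_G GG^\top + w_S S_sS_s^\top + w_K K_kK_k^\top +
  w_{SK} I_{sk}I_{sk}^\top + w_E I,$$

with each factor an `n_units × latent_rank` standard-normal matrix drawn
once per cohort (rank 5 by default). A parcellation with `n_nodes` nodes
partitions the units into contiguous balanced blocks; a node's series is
the mean of its units plus node-level measurement noise of fixed standard
deviation `node_noise_sd`, band-passed and offset by `baseline` (100
arbitrary units, which keeps tSNR and percent-change global-signal
thresholds meaningful). Because unit-level draws depend only on
`n_units` and the seed, the same seed observed at two `n_nodes` values is
literally the same cohort at two granularities — which is what makes
parcellation sweeps, stratified down-sampling and tSNR comparisons
internally consistent: coarse nodes average more units, so their
fluctuations shrink against the fixed measurement noise (higher tSNR,
blurrier individual signal), while fine nodes retain more distinct signal
(lower tSNR, better identification). Both directions emerge from the
construction rather than being injected per experiment.

Motion spikes (rate `motion_spike_rate` per volume, never the first
volume) set framewise displacement to 0.5–1.5 mm and offset the whole
volume so the global signal jumps by at least 7% of the scan mean relative
to the previous volume — guaranteed even for consecutive spikes by
steering the offset walk — plus node-level noise at 3× the median node
standard deviation, centered across nodes so the phase pattern is
corrupted without altering the controlled global jump.

What the generator does **not** emulate: hemodynamics (no HRF
convolution), spatial structure (no voxels, images or atlas geometry),
physiological rhythms (cardiac/respiratory aliasing), scanner drift, or
realistic effect sizes. The mixture weights are free parameters, not
estimates of real individuality; passing tests demonstrate the pipeline's
correctness and its qualitative behavior under controlled signal
structure, not quantitative accuracy levels expected on real data.

## Preprocessing choices

* **Pipeline order** is fixed: steady-state drop → motion flagging (from
  the raw traces) → band-pass → confound regression. Regression is
  idempotent (residual of residual equals residual, tested at 10⁻⁸).
* **Filter**: zero-phase (forward–backward) 2nd-order Butterworth
  band-pass, 0.009–0.08 Hz by default. Zero-phase filtering is essential
  because phase distortion would corrupt the Hilbert phases downstream; a
  cross-correlation test asserts zero lag for in-band sinusoids. A
  residual post-filter demeaning removes the tiny DC left by finite-length
  transients. Series shorter than 30 volumes are rejected.
* **Confounds**: the scan's global mean signal (toggleable — global
  signal regression remains debated, so both variants run) and the binary
  high-motion indicator, regressed per node with an intercept; collinear
  columns are dropped with a warning.
* **Motion flag**: a volume is flagged iff framewise displacement ≥
  0.5 mm *and* absolute global-signal change from the previous volume ≥
  5% — a conjunction, so neither condition alone flags. The 5% is taken
  relative to the scan's mean global signal, because a previous-frame
  denominator is unstable once signals are demeaned. Framewise
  displacement is consumed as a given trace; no rigid-body parameters are
  computed (there are no images in scope).
* **tSNR** (temporal mean / temporal SD) is computed on the raw,
  unfiltered, unregressed series, since filtering rescales variance and
  would make granularity comparisons uninterpretable; zero-variance nodes
  are reported as undefined and excluded from averages.

## Numerical conventions in the phase stage

* Phases are wrapped to (−π, π]; constant node series are an error naming
  the offending node.
* The first and last 5 volumes are trimmed after the Hilbert transform
  (configurable), which removes its edge artifact; flags and traces are
  trimmed identically so indexing stays aligned.
* Eigenvector sign is fixed so the largest-magnitude entry is positive —
  purely for reproducible serialization, since all downstream similarity
  uses absolute correlation and a sign-invariance test confirms nothing
  depends on it.
* The time collapse uses eigenvalue-weighted outer products by default, so
  each volume contributes its actual energy and the collapsed matrix
  tracks the static Pearson network (off-diagonal correlation ≥ 0.9 on
  band-limited synthetic scans); the unweighted sum is available via
  `collapse_time(..., weighted = FALSE)`.

## Identification conventions

* **Argmax ties** (exactly equal similarities) break toward the
  lexicographically lowest (subject, session, task, volume), with a
  warning; ties have measure zero on continuous data but occur with
  constructed duplicates.
* **Scan-vote ties** break toward the label with the larger summed
  similarity over its winning volumes, using available evidence instead of
  arbitrary order.
* **Permutations** shuffle database *scan* labels (volumes keep their
  scan's permuted label), preserving label counts as a multiset;
  permutations are sampled with replacement from the permutation group. A
  zero exceedance count is reported as "< 1/n_perm" rather than 0.
* **Uncertainty**: the package reports permutation p-values and percentile
  bootstrap confidence intervals over target scans (2000 resamples by
  default) instead of fitting mixed-effects models; the permutation null
  is the protocol-defined significance test, whereas a mixed model would
  be an off-the-shelf fit outside this package's contribution.
* The similarity search streams database scans one at a time, so the full
  volumes × volumes similarity matrix is never materialized.
* `run_identification` evaluates every (target session, size-k database
  subset) combination, so the combinatorics (e.g. 126 = C(9,5) databases
  per target session at k = 5 with 10 sessions) match the protocol
  arithmetic exactly.

## Chance bands for exchangeable cohorts

Band-limited signals are temporally correlated: at TR 2.2 s and an upper
band edge of 0.08 Hz, a scan of T volumes carries roughly
2 × 0.08 × 2.2 × T ≈ 0.35 T independent samples (the Nyquist rate of the
band-limited process). Tests that check a zero-signal cohort stays at
chance therefore use a binomial band with this effective sample size
rather than the raw volume count, which would be anti-conservative. The
factor is fixed from the band edges a priori, not fitted.

## Problem sizes

The test suite and examples run on deliberately small cohorts — typically
3–10 subjects, 2–4 sessions, 30–50 nodes (500 for parcellation
contrasts), 60–160 volumes, 100–800 latent units — chosen so the full
suite completes in about a minute while every protocol component
(subsets, sweeps, permutations, down-sampling) is exercised end to end.
The study-shaped presets (`cohort_preset()`) retain the real dimensions —
10×10 sessions with 818-volume scans, 100×6 with 274, 173×2 with 217 —
so chance expectations (80.3, 2.59, 1.14 volumes; 35.3 for three tasks)
and volume bookkeeping (818 → 813 → 803; 121 → 116 → 106; 274 → 269 →
259; 217 → 207 → 197) reproduce the protocol arithmetic exactly.

## Known limitations

* Instantaneous phase is only meaningful for narrowband signals; the
  package warns through its preconditions but cannot rescue a broadband
  input.
* Phase coherence discards amplitude: volumes with very different signal
  energy can have identical coherence patterns.
* The rank-2 structure (and hence the ≥ 50% variance guarantee) is a
  property of the cosine-difference construction, not of BOLD data; any
  preprocessing applied *after* phase extraction would break it.
* Node-level input granularity means voxel-level preprocessing
  (segmentation, normalization, slice timing) is out of scope and assumed
  done upstream.
* Synthetic accuracies are not forecasts of real-data accuracies; they
  validate directions of effect (more database sessions, finer
  parcellations, within- vs between-subject task structure, motion
  corruption), not magnitudes.
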