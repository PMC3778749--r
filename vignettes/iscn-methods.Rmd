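---
title: "Individual structural connectivity networks: model, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual structural connectivity networks: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscn)
```

## The problem

Diffusion-weighted MRI (DWI) measures how water diffuses in tissue. In white
matter, diffusion is fastest along axon bundles, so a per-voxel diffusion
tensor summarizes the local fiber orientation and coherence. Following
streamlines through the tensor field (tractography) yields estimated fiber
trajectories; counting streamlines between pairs of atlas regions turns a
brain into a weighted graph — an individual structural connectivity network
(ISCN). Groups of subjects (for instance patients versus controls) can then be
compared by classifying these networks edge-wise, which both predicts group
membership and points at the connections that carry the difference.

`iscn` implements this whole chain — tensor fit, tensor-deflection (TEND)
deterministic tractography, atlas-based network construction with
fiber-density/FA/MD edge weights, and cross-validated two-group classification
with information-gain feature selection — together with a synthetic phantom
generator, so every stage can be validated end-to-end with known ground truth
and no scanner data.

## Signal model and tensor fit

A single-shell acquisition is described by a gradient table: `K` pairs of
b-value (s/mm²) and unit direction. The default scheme
(`default_gradient_table()`) uses 15 approximately uniform noncollinear
directions at b = 800 s/mm² plus one b = 0 baseline, a typical clinical
single-shell protocol.

Signals follow the single-tensor Stejskal–Tanner model

$$ S_k = S_0 \exp(-b_k\, g_k^\top D\, g_k), $$

with `D` a symmetric positive-semidefinite 3×3 tensor in mm²/s.
`fit_tensor()` solves the log-linearized system
$\ln S_k = \ln S_0 - b_k g_k^\top D g_k$ by ordinary least squares over the six
unique tensor elements plus the log baseline, per voxel, vectorized across the
volume. Choices made here:

* **OLS, not weighted/nonlinear.** With noiseless or high-SNR single-shell
  data the log-linear system is exact, fast and has no tuning parameters.
  On noiseless phantoms the fit recovers ground-truth tensors to ~1e-16
  mm²/s, far below the 1e-9 tolerance the test suite asserts.
* **Degenerate voxels.** Any voxel with a non-positive signal is flagged
  invalid and carries a zero tensor. Negative eigenvalues (possible under
  noise) are clamped to zero before FA/MD and flagged, keeping FA in [0, 1].
* **All-zero eigenvalues define FA = 0** rather than NaN, so empty voxels
  never poison downstream tracking masks.
* Multiple b = 0 volumes are averaged into one baseline before fitting.

From the eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$:

$$ \mathrm{FA} = \sqrt{\tfrac12}\,
   \frac{\sqrt{(\lambda_1-\lambda_2)^2 + (\lambda_2-\lambda_3)^2 + (\lambda_3-\lambda_1)^2}}
        {\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}},
 \qquad \mathrm{MD} = \frac{\lambda_1+\lambda_2+\lambda_3}{3}. $$

## TEND tractography

`track_whole_volume()` seeds one streamline at the center of every voxel with
FA **strictly above 0.3** and propagates it in both directions, starting along
±e₁ of the seed tensor. At each step the incoming unit direction is deflected
by the full local tensor,

$$ v_\mathrm{out} = \mathrm{normalize}(D\, v_\mathrm{in}), $$

with the sign chosen so $v_\mathrm{out} \cdot v_\mathrm{in} \ge 0$. A
half-track terminates when the next position would leave the grid, lie in a
voxel with FA **strictly below 0.2**, or require a turn above 60°; a step cap
(default 2000) guards against cycles. Default step size is half the smallest
voxel dimension. All thresholds are strict inequalities, exactly as printed in
the tracking literature this mirrors.

Further choices:

* **Pure deflection.** The TEND family blends e₁, v_in and D·v_in; the
  package exposes the blend weights (`f`, `g`) but defaults to the pure
  deflection `f = 0, g = 1`, the minimal reading when no blend is specified.
* **Nearest-voxel lookup, no interpolation.** Stopping is phrased per voxel
  ("tracking stops in voxels with ..."), so the tensor and FA at a point are
  those of its containing voxel (continuous index rounded by `floor(c + 0.5)`;
  cells are half-open).
* **Only validated points join the streamline.** A candidate point that fails
  the bounds or FA test terminates the half-track *without* being appended,
  so every retained point lies in a suprathreshold voxel — this is what lets
  endpoints fall inside the labeled end-cap regions rather than one step past
  them.
* **Junction exemption.** The two half-tracks launch at 180° by design, so
  the junction between them is exempt from the curvature test
  (`junction_index` records it).

A geometric fact worth knowing when designing phantoms: pure deflection turns
an incoming direction by at most $90° - 2\arctan\sqrt{\lambda_2/\lambda_1}$
in a single step, no matter how sharply the underlying bundle bends. With the
default in-bundle eigenvalue ratio 0.18 that maximum is ≈ 45°, below the 60°
stop. The sharp-bend phantom therefore uses a more prolate tensor
(ratio 0.035, single-step turn ≈ 69° at its 80° bend) so that the bend
actually exercises the curvature rule — that phantom's defining property is
that the only >60° turn happens at mid-bundle.

## Parcellation

`threshold_probabilistic_atlas()` reproduces the standard
probabilistic-atlas-to-labels step: a voxel is assigned to the region with the
highest probability among those **strictly above 35%** (configurable), and to
background if none passes. Assigning by argmax guarantees non-overlapping
regions (the stated reason for thresholding at 35% in the emulated protocol);
exact ties break to the lowest region index so the operation is deterministic.
`resample_labels()` carries a label volume through a given affine (template ↔
native) by nearest-neighbor lookup — labels are never interpolated, and
registration *estimation* is deliberately out of scope: transforms are inputs,
and phantoms use the identity.

## Network construction

`build_network()` combines a tractogram, a label volume and the tensor field:

* `n_ij` — streamlines whose two terminal points fall in regions i and j
  (endpoint voxel by flooring the continuous index; background or same-region
  endpoints contribute nothing);
* `n_all` — the total number of streamlines launched, including those that
  contribute no edge;
* fiber density `cd_ij = n_ij / n_all`;
* `FA_ij`, `MD_ij` — the mean FA/MD over the **deduplicated union** of voxels
  visited by all streamlines of the edge. Counting each voxel once (rather
  than once per visit or per streamline) prevents heavily revisited voxels
  from dominating the mean; this is a documented choice, as the emulated
  protocol does not state its weighting.
* the connection threshold `m` (1 by default; 3 and 5 as robustness variants):
  edges with `n_ij < m` carry **exact 0** in density, FA and MD. Zeros rather
  than missing values give every subject the same fixed-length feature vector,
  and 0 is the natural "no measured connection" value. Raising `m` never adds
  an edge and never changes a surviving edge's value (tested property).

## Feature selection by information gain

Each attribute's network vectorizes to the R(R−1)/2 upper-triangle edges in
lexicographic order. For a candidate feature, `information_gain()` measures
the reduction in class entropy after discretizing the feature by recursive
entropy-minimizing binary splits with the Fayyad–Irani MDL stopping rule,
computed **on the training subjects only**, in bits.

One wrinkle deserves a note. A feature with exactly two distinct values has an
unambiguous discretization — the single possible cut — and rejecting it by the
MDL test (which is very conservative at small n) would discard even a
perfectly class-separating binary feature. The package therefore accepts the
single cut of a two-valued feature unconditionally and applies the MDL test to
every split of richer features, including the first. Continuous noise features
consequently score 0 most of the time (the selection stays sparse, which the
protocol validity checks rely on), while binary indicators are scored by their
plain information gain.

`select_features()` ranks by gain (ties to the lower edge index) and by
default keeps all features with positive gain; the cross-validation harness
falls back to all features if the selection is empty. Edges selected in
**strictly more than** 5 validation rounds form the "highlighted" set that
marks candidate discriminative connections.

## Classifiers

Three standard two-class predictors operate on the selected edges:

* **Maximum-margin (soft-margin SVM, linear kernel).** Features are
  standardized with training-fold means/sds (sd floored at 1e-12); the
  quadratic program is solved by libsvm via `e1071`, and the explicit
  normal vector and offset are extracted so prediction is
  `sign(w'x + b)` with 0 mapped to the positive (first) class. The kernel is
  linear and C = 1 by default — both unreported in the emulated protocol and
  exposed as configuration.
* **k-NN with Pearson-correlation similarity, k = 6.** Majority vote of the
  six most correlated training subjects; vote ties break by summed
  similarity, then by the most similar neighbor. Correlations with constant
  vectors are undefined and treated as 0 with a warning.
* **Gaussian naive Bayes.** Per-class, per-feature Gaussian conditionals
  with variances floored at 1e-9 of the pooled variance; prediction maximizes
  `log p(c) + Σ log p(x_i|c)` in log space; exact ties break to the larger
  prior, then the lower class index.

## Validation protocol

`run_cv()` runs, per comparison and per attribute, stratified 10-fold (or
leave-one-out) cross-validation with the entire feature selection nested
inside each training fold — the held-out subjects influence nothing about the
round that predicts them, which is asserted by recomputation in the tests.
Accuracy is pooled as total correct over total subjects rather than averaged
over folds: pooling makes every reported accuracy an exact integer multiple of
1/n, the granularity printed by classification tables of this kind (e.g.
43/44 = 97.73%, 35/38 = 92.11%, 34/40 = 85.00%), which a mean of unequal
fold accuracies generally cannot produce. Folds are stratified by class with
a seeded shuffle, since unbalanced small groups otherwise risk single-class
training folds.

## What the synthetic data emulates — and what it does not

`make_bundle_phantom()` produces voxel-level DWI of a single coherent fiber
bundle (straight, smoothly curved, sharply bent, or two crossing bundles) with
known tensors, optional Rician noise (|signal + complex Gaussian| with
per-channel sd `s0/snr` — the standard MR magnitude-noise model), and labeled
end-caps. It does **not** emulate realistic head geometry, partial-volume
mixtures, crossing-fiber signal models beyond the simple two-bundle overlap,
or susceptibility/eddy/motion artifacts. Passing phantom tests therefore
demonstrates the correctness of the algorithms, not robustness to real
acquisition physics.

`make_cohort()` generates two-group cohorts of connectivity matrices directly:
a common edge support (each edge present with probability 0.5), per-edge
baseline means (log-normal across edges for fiber density, normal for FA/MD,
coefficient of variation 0.35) and per-edge sds (uniform 0.5–1.5 × the
attribute sd), shared by all subjects; subjects draw independently around
those baselines, and a chosen number of edges receive a mean shift of
`effect_size_d` per-edge standard deviations in group 2. The heterogeneity
across edges mirrors real connectomes, where fiber density spans orders of
magnitude and FA/MD differ systematically by tract; a first design with
homogeneous edges was discarded because it makes the planted effect a
constant offset of the feature vector, which Pearson-correlation similarity
cannot see at all. Missing edges are exact 0 in all attributes, matching the
network builder's encoding. Default conditions: 16 regions (120 edges),
20 + 20 subjects, 10 planted edges.

### Protocol validity results the package itself computes

* **Null cohorts** (`type_one_check()`, d = 0, 50 seeds): mean pooled CV
  accuracy falls inside the 95% binomial interval around 0.5 — the nested
  selection leaks nothing.
* **Planted effects** (d = 2, 10 edges, 20 seeds): the maximum-margin and
  naive Bayes classifiers recover the groups almost perfectly, and the edges
  highlighted by the >5-rounds rule are almost exclusively the planted ones.
* **Known limitation — correlation k-NN on uniform shifts.** Pearson
  similarity centers and scales each subject's feature vector, so a shift
  that is (in standardized magnitude) uniform across the selected edges is
  largely invisible to it; only the per-edge variation of the shift remains
  as signal, and with ~10 selected features the sampling noise of a
  correlation dominates. Under the planted-effect conditions above, k-NN
  reaches ≈ 0.77 rather than the ≥ 0.9 of the other two classifiers. This is
  a structural property of correlation similarity under this effect model,
  not an implementation defect; on pattern-type differences (direction rather
  than level) k-NN separates perfectly, as the classifier tests show.

## Numerical and problem-size choices

Phantom grids default to 40×20×20 voxels (2 mm isotropic) for the straight
bundle and 30×30×14 for the curved ones; the end-to-end pipeline demo uses
24×12×12 with 6 + 6 noisy subjects (SNR 25); group 2's bundle is thinner and
its in-bundle FA (~0.32) sits just above the seed threshold, so under noise
its tracking partially fails — the group difference then shows in fiber
density as well as FA/MD (a strongly anisotropic bundle saturates density
at ~1 in both groups). On a 2-region network there is a single edge feature,
on which Pearson similarity is undefined (treated as 0), so the k-NN
classifier is uninformative in this demo by construction. These sizes keep
each analysis script in the
seconds-to-minutes range while leaving every geometric property intact:
all thresholds, step sizes and stopping rules are in physical units and do
not depend on grid size. All randomness (noise, cohort draws, fold shuffles)
flows through explicit integer seeds, and every generator restores the
caller's RNG state, so runs are bit-reproducible.

## Known limitations

* Single-tensor model only: no multi-shell, kurtosis or free-water variants.
* Deterministic tracking only; no probabilistic or anatomically constrained
  variants, and no streamline pruning.
* Registration is consumed, never estimated.
* Graph-theoretic summaries (path length, clustering, ...) are deliberately
  absent: the classification operates on the full multivariate edge pattern.
* Two-class comparisons only, mirroring the emulated study design.
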