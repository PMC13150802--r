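---
title: "Reducing a cross-reactive sensor array: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing a cross-reactive sensor array}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensortrim)
```

## The statistical model

A screening experiment yields fractional responses `X` (n samples x p
sensors) and analyte labels `y` in 1..K, with very few replicates per
class (n_k of 3–5 is typical). sensortrim assumes each class is Gaussian
in sensor space; since principal components are linear maps, classes
stay Gaussian in the PC1–PC2 plane where all decisions are made. The
whole pipeline is supervised and uses no hold-out set: the reported
error is the overlap of each fitted class Gaussian with the *other*
classes' decision regions, i.e. a geometric separability measure under
the fitted uncertainty model, not a cross-validated generalization
error. That is a deliberate trade: with 3–5 replicates per class a
hold-out estimate is dominated by partition noise, while the overlap
integral is smooth in the class moments and comparable across
elimination iterations.

### Finite-sample predictive inflation

Plug-in moment estimates from n_k replicates understate the spread of a
*future* observation. Along each class-local principal axis with
unbiased sample variance s², the package uses the posterior predictive
variance

    sigma2_pred = s2 * (1 + 1/n_k) * (n_k - 1)/(n_k - 2),   n_k > 2,

the `(1 + 1/n_k)` factor accounting for the unknown mean and
`(n_k-1)/(n_k-2)` for the unknown variance. The factor is 1.6 at
n_k = 5 and decays to 1 as replicates accumulate. The diagonal of
inflated axis variances is rotated back to the global PC frame, so the
class ellipse grows along its own principal directions without changing
orientation. For n_k = 2 the variance-uncertainty factor diverges
(a two-point sample carries almost no information about its variance),
so only the unknown-mean factor is applied and the remaining
uncertainty is delegated to shrinkage and the eigenvalue floor; this
keeps the estimate finite, conservative, and continuous in spirit with
the n_k > 2 branch.

### Shrinkage and eigenvalue conditioning

Off-diagonal covariance entries are the least stable quantities at
these sample sizes, and QDA geometry is sensitive to them. Each
inflated class covariance is therefore blended toward the pooled
(degrees-of-freedom-weighted) covariance with a per-class
Ledoit–Wolf-style intensity

    lambda_k = min(1, max(0, b2_k / d2_k)),

where `b2_k` is the summed sampling variance of the class covariance
entries, estimated from the centered class scores as
`(1/n²) Σ_i ||z_i z_iᵀ − S_ml||²_F`, and `d2_k = ||Σ_k − Σ_pooled||²_F`
is the squared distance to the target. This is the standard plug-in
intensity adapted to a pooled target; other intensity estimators would
slot in behind the same function (`shrink_and_condition()`) without
touching the rest of the pipeline. Afterward every eigenvalue is
clipped from below at `max(1e-6 x largest pooled eigenvalue, 1e-12)` —
scale-aware, so the floor neither dominates well-conditioned problems
nor underflows tiny ones — guaranteeing symmetric positive-definite
covariances and stable discriminants even for rank-deficient classes
(two collinear replicates). In 1D mode all of this collapses to scalar
variances.

### Decision models

QDA is the default: per-class covariances give curved boundaries that
handle unequal class shapes. The discriminant is the standard

    g_k(x) = -1/2 log|Sigma_k| - 1/2 (x - mu_k)' Sigma_k^{-1} (x - mu_k) + log pi_k

with uniform priors (screening designs are replicate-balanced).
Voronoi (nearest centroid) is retained as a fast piecewise-linear
alternative; under equal isotropic covariances the two coincide
exactly.

**A caution on covariance scaling.** It is tempting to assume that
multiplying *all* class covariances by a common factor c leaves QDA
labels unchanged, which would make the inflation step irrelevant to the
boundary geometry. That invariance holds for the Mahalanobis part of
the discriminant but not for the full rule: the pairwise boundary
solves `m_k(x) − m_j(x) = −c·(log|Σ_k| − log|Σ_j|)`, which moves with c
whenever the class determinants differ. It is exact only in the
equal-determinant (e.g. equal-covariance/LDA) limit or for a
determinant-free nearest-Mahalanobis rule. sensortrim keeps the full
QDA discriminant — dropping the log-determinant would, among other
things, eliminate the two symmetric thresholds that separate an
equal-mean, unequal-variance class pair — and the test suite records
the scaling property honestly: it passes for Voronoi and for
equal-determinant QDA, and fails for general covariances.

### Error, ARI and separation traces

Per-class error is estimated by drawing `mc_samples` points from the
class Gaussian and classifying them by direct discriminant evaluation
(the raster grid exists only for visualization; classifying through it
would add quantization error). The mean error e(l) is the unweighted
per-class average, in percent. ARI(l) is the adjusted Rand index
between the true labels and the classifier's labels on the measured
training samples — with no hold-out set it measures in-sample
consistency of the fitted partition. ⟨D⟩(l) is the mean pairwise
Euclidean distance between class centroids in the PC plane.

Ties in classification (a point exactly equidistant, or two identical
class models) resolve to the lowest class index. This makes runs
deterministic, with one visible consequence: two *identical* class
Gaussians tie everywhere, so the lower-indexed class absorbs all the
mass and the pair's errors are (0, 1) — the 50% mean correctly reflects
complete overlap, but it is not split 0.5/0.5 per class.

### Sensor scoring and elimination

For each sensor, classes are ordered by increasing mean response and a
threshold is placed between each consecutive pair: the midpoint under
Voronoi, or the 1D QDA boundary otherwise (variances inflated and
regularized exactly as in 2D; when the quadratic has no real root
between the two means, the midpoint is the fallback). The resulting
"ruler" discretizes the sensor's readings into decision-aware bins,
concentrating resolution where it matters. Values exactly on a
threshold go to the left bin; duplicate thresholds from coincident
class means are deduplicated, leaving those classes in a shared
interval.

Uniform selection (uFS, default) ranks sensors by Pearson's chi-squared
between bins and labels; a degenerate contingency (one occupied bin)
scores 0. Weighted selection (wFS) recomputes the statistic per class
pair on the same bins and averages with weights proportional to
1/Δ(a,b), so nearly confusable pairs dominate. Δ(a,b) is the distance
between class sample centroids along the sensor axis (zone centroids
from the fitted decision model are an alternative; sample centroids
were chosen as the more robust of the two at n_k ≤ 5, and the `deltas`
argument lets callers supply their own). Zero separations are capped at
`1e-9 x data range`, giving coincident pairs a large but finite weight.
The lowest-scoring sensor is removed (ties: earliest column), rulers
and boundaries are rebuilt on the survivors, and the loop runs until
one sensor remains.

### Working point

The array size is chosen by minimizing `J(l) = e(l) + eta*l`, with e in
percent and eta in percent per sensor. The defaults eta = 3 and
eta = 0.5 represent sparsity-leaning and accuracy-leaning regimes.
Cost ties go to the smaller l. `eta_sweep()` traces l*(eta), which is
provably non-increasing in eta.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `classifier` | `qda` | — | curved boundaries for unequal class covariances; `voronoi` for speed/linearity |
| `fs_mode` | `uniform` | — | plain chi-squared ranking; `weighted` emphasizes confusable pairs |
| `inflation` | `adjusted` | — | finite-sample predictive inflation on; `unadjusted` reports raw-scatter (optimistic) errors |
| `ev_flag` / `ev_threshold` | off / 0.95 | fraction | switch to 1D decisions when PC1 > threshold (strict `>`); off by default to keep 2D maps |
| `etas` | 3, 0.5 | % error per sensor | sparsity-leaning and accuracy-leaning working points |
| `mc_samples` | 1e5 | draws/class | MC standard error ~0.1% at 1e5; floor of 1e3 enforced |
| `grid_resolution` | 400 | cells/axis | raster export resolution only; never used to classify data |
| `ellipse_level` | 0.95 | coverage | chi-squared(2 dof) quantile 5.991 sets the ellipse axes |
| `seed` | 1 | — | root of all randomness; per-iteration, per-class MC seeds derive from it |

## What the synthetic generator does and does not emulate

`generate_dataset()` draws each class from a specified Gaussian —
matching the pipeline's own model assumption. `planted_recovery_spec()`
places K class means on a circle in the informative-sensor subspace
(scaled so the minimum pairwise separation is as requested) and gives
noise sensors identical means, creating a ground truth for recovery
experiments. `inflate_stress_dataset()` resamples classes from a fitted
baseline with means fixed and covariances scaled by the squared
inflation factor (50 replicates per class by default, factors 2/5/10),
holding the baseline PCA loadings fixed by projecting the PC-plane
samples back through them; inflation is re-estimated on the resampled
replicates, where at n = 50 the correction is negligible.

Because generator and model share the Gaussian assumption, passing
tests demonstrate correctness of the machinery — recovery of planted
structure, monotone degradation under inflation, agreement with
closed-form overlaps — not robustness to what real screening data add:
non-Gaussian and heteroscedastic noise, drift and batch effects,
correlated sensor failures, and class distributions that are only
approximately Gaussian after the fractional-response transform.

## Numerical and design choices

- **Fractional response** is `(I − I0)/I0`; tables may also be supplied
  already normalized. Sensors are mean-centered, never scaled to unit
  variance — relative response magnitude is part of the fingerprint.
- **PCA sign convention:** each component's largest-magnitude loading
  is made positive, so repeated runs and row permutations give
  identical score signs. PCA is recomputed on the surviving subset at
  every iteration.
- **Missing values are rejected**, not imputed: screening tables are
  small and silent imputation would bias class moments.
- **Determinism:** one root seed; MC seeds derive from (seed, iteration,
  class); identical input + config + seed give byte-identical CSVs.
- **Degenerate inputs:** identical-point classes get zero variances and
  an identity local frame (repaired by the floor); rank-0 tables are
  rejected; single-sensor tables use the 1D path throughout.
- **Problem sizes in the test suite** mirror the intended screening
  regime — 3–6 classes, up to 30 sensors, 3–5 replicates per class —
  with 1e3–1e4 MC draws in tests whose outcome does not depend on MC
  resolution (the elimination path is chi-squared-driven and therefore
  MC-independent), and 1e5 draws where an estimator is compared to a
  closed form.

## Known limitations

- Decisions live in at most two principal components; arrays whose
  class structure needs PC3+ lose information, and automated
  dimensionality selection is future work.
- The error is an in-model overlap integral: it inherits the Gaussian
  assumption and says nothing about out-of-distribution analytes.
- Greedy backward elimination is not globally optimal; it can discard a
  sensor whose value only appears in combination with later removals.
- ARI is computed on training samples; with n of a few dozen it is a
  coarse, optimistic summary.
- The Ledoit–Wolf intensity is a plug-in estimate from very few
  replicates; it is clipped to [0,1] and is itself noisy, which is why
  the eigenvalue floor backs it up.
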