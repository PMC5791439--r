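---
title: "Orthogonal remodeling components: model, assumptions and design choices"
author: "lvremodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthogonal remodeling components: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvremodel)
```

## The problem

Left-ventricular (LV) remodeling — the adaptation of ventricular size, shape
and function to disease — is routinely quantified by scalar clinical indices:
end-diastolic volume index (EDVI), sphericity, ejection fraction (EF),
relative wall thickness (RWT), apical conicity and longitudinal shortening
(LS). These indices have prognostic value but are strongly interrelated
(dilated ventricles eject less; spherical ventricles have relatively thinner
walls), which makes it hard to attribute shape change to one process.

Given per-subject surface models in homologous point correspondence, this
package decomposes LV shape space into *orthonormal* components, each tied to
one clinical index, so that the amount of each remodeling process in a given
heart can be read off as a projection.

## Model

Let `X` be the N x P matrix of flattened, column-centered shape vectors (P =
all x,y,z coordinates of both surfaces at both frames) and `y` a centered
clinical index. Partial least squares regression with `M` latent factors
gives

    y = X b' + e

with the latent factors chosen to maximize the covariance between response
and predictors (SIMPLS). The unit vector `b = b'/||b'||` is the *remodeling
component* for that index, and the *remodeling score* of a subject is the
projection `X b`. An estimated index is recovered from a score by
`score * ||b'|| + mean(y)`.

Components are extracted sequentially. After each extraction the shape
matrix is deflated,

    X <- X - X b b',

so every later component is orthogonal to `b` by construction; the K
components form an orthonormal basis of a K-dimensional subspace of shape
space (`remodel_decompose()`, with `coef()`, `predict()`, `residuals()`,
`summary()` and `plot()` methods).

Two properties matter and are enforced by tests rather than assumed:

* **`M = 1` is special.** The single-factor coefficient is exactly
  proportional to `t(X) %*% y`. Deflating along it annihilates the
  cross-covariance of the residual shape space with `y`, so the scores of
  every *later* component have exactly zero correlation with every *earlier*
  index, and the score-score correlations drop well below the raw
  index-index correlations (the EDVI-EF pair is the flagship example).
* **Larger `M`** tracks each index more faithfully (higher diagonal
  correlation) at the cost of re-importing the indices' mutual correlation
  into the scores. `cross_validate_M()` shows the prediction error flattens
  around ten factors; the package treats `M = 1` and `M = 10` as the two
  regimes of interest.

Extraction order follows decreasing remodeling-score variance. The default
is the fixed order `edvi, sphericity, ef, rwt, conicity, ls` established on
the reference cohort; `order = "auto"` recomputes the one-step score variance
greedily on the current residual at every step (ties broken alphabetically).
On the synthetic cohorts below, greedy ordering picks sphericity first: a
volume-preserving sphericity change displaces every longitudinal coordinate
and therefore moves more point mass than a pure size change, even though the
index itself varies little. The fixed order is retained as the default
because it reflects the reference-population ranking and makes the first
component the size component.

## Clinical indices

All indices are computed from the triangulated surfaces (`close_surface()`
adds centroid-fan caps at base and apex so volumes are well defined;
`surface_volume()` sums signed tetrahedra). Conventions the source
definitions leave open were fixed once:

* **BSA**: Mosteller, `sqrt(height * weight / 3600)` — fewest constants,
  standard in cardiology.
* **Diameter** of a ring: twice the mean distance to the ring centroid
  (exact for circles, robust to grid anisotropy).
* **Apex**: the grid point farthest from the basal plane along the
  base-to-apex direction, not the last ring centroid.
* **Posterior sector** for RWT: the quarter of the mid-ventricular ring
  centered on the template's posterior (-y) direction, selected by
  circumferential index so the measure is rigid-motion invariant.
* **"One-third above the apex"** ring for conicity: selected by arc position
  along the long axis, robust to nonuniform ring spacing.
* **Units**: mm internally; volumes in ml, mass in g (wall volume times
  1.05 g/ml), EDVI in ml/m^2; EF, RWT, sphericity, conicity and LS as
  fractions (reference tables print RWT and LS in percent).

EF, EDVI-from-EDV and the scale behaviors (`edvi ~ s^3`, the five ratio
indices scale-invariant) hold exactly by construction and are tested as
invariants.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the package ships a
generator (`generator_config()`, `generate_cohort()`) whose draws stand in
for them in every test. The template is a truncated superellipsoid shell:
ring `j` sits at longitudinal fraction `u`, `z = -L u`, with radius
`r(u) = r_b (1 - u^p)^(1/p)`; the epicardium adds a wall offset `t`; the ES
frames apply radial and longitudinal contraction factors about the basal
plane. Six unit-variance Gaussian latents drive the six indices through
exponential links (positive parameters) or logistic links (contraction
fractions in (0,1)):

| latent | parameter | index driven |
|---|---|---|
| size | global scale `s` | EDVI |
| sphericity | `r_b` up, `L` down, cavity volume preserved | sphericity |
| thickness | `t` (co-scaled with `s`) | RWT |
| taper | profile exponent `p`, radius compensated to preserve volume | conicity |
| radial | ES radial factor | EF |
| longitudinal | ES longitudinal factor, radial factor compensated to preserve ES volume | LS |

The compensations are the key design choice: they make each latent drive
exactly one index (a size change is the only way to change cavity volume; a
longitudinal-shortening change cannot move EF), which keeps the generative
directions identifiable from shape data. Because the ES frame is an affine
image of the ED frame, EF equals `1 - lr^2 * lL` exactly, mesh and all.

**Calibration.** `calibrate_generator()` is a coordinate search that
repeatedly simulates a cohort, pushes the template parameters toward the
reference asymptomatic index means, the loadings toward the asymptomatic
SDs, and the MI latent shifts toward the MI means — always through the full
triangulated-surface index pipeline, so discretization effects are absorbed
into the calibrated values. The shipped `generator_config()` defaults are
the frozen output of one such run (1500-3000 subjects per draw, six damped
sweeps); fresh draws at n = 1000 land within about 2% of every target mean.
Group sizes default to the reference 1991 asymptomatic + 300 MI; point noise
defaults to 0.5 mm.

**What the generator does not emulate.** Latents are independent within
group (as specified), so within-group index correlations are near zero,
unlike real cohorts where EDVI and EF correlate strongly within the
asymptomatic population. Two consequences, documented rather than hidden:

* Pooled-cohort correlations arise only from the group contrast, so
  correlation tables are qualitatively, not quantitatively, comparable to
  the reference ones.
* The calibrated group mean shifts put the two classes roughly 4.8 pooled
  SDs apart in score space: the groups are *completely separable*, and
  maximum-likelihood logistic regression on the scores is degenerate —
  `fit_logistic()` raises its separation error, which is the documented
  behavior. Discrimination on the synthetic cohorts is therefore higher
  (AUC ~ 1) than the reference AUC ~ 0.97. Tests that need a finite
  logistic fit flip ~10% of labels, emulating diagnostic misclassification.
* MI-group SDs are not independently matchable with group-shared loadings;
  only the means (and asymptomatic SDs) are calibrated.

Ground truth is recorded per cohort: the latent draws and the unit
generative directions (central finite differences of the flattened template
at the population mean, `true_component_directions()`).

**Parameter recovery.** Because ratio indices have generative directions
that overlap the size direction (any fixed-volume sphericity change
displaces every z coordinate), components extracted under Gram-Schmidt
deflation estimate the *sequentially orthogonalized* generative directions,
not the raw ones; the first (size) component is the one case where the two
coincide. Recovery is assessed on the homogeneous asymptomatic group, where
latents are independent: at 0.5 mm noise and n = 500, the size component
lands within 5 degrees of the true size direction and all six components
within 15 degrees of their orthogonalized targets.

## Logistic characterization

`fit_logistic()` wraps binomial IRLS (`stats::glm`, relative-deviance
convergence, 100 iterations) and reports the clinical-table columns: Wald
SEs and p-values, standardized coefficients (coefficient times predictor SD;
binary covariates coded 0/1 and left unscaled), odds ratios with Wald 95%
CIs, and deviance/AIC/BIC (`aic = deviance + 2k`, `bic = deviance + k log
n`). Separation is detected by a diverging standardized-coefficient norm and
raised as an error rather than returned as a fit. `compare_models()`
tabulates deviance/AIC/BIC/AUC and pairwise one-sided DeLong tests
(`pROC::roc.test`); `auc()` itself is the Mann-Whitney statistic with ties
counted one half. `group_median_shape()` rebuilds, per group, the shape at
the group's median logistic-regression score along the standardized
coefficient combination of components — the shape contrast that best
separates the groups after covariate adjustment.

## Numerical choices

* Meshes are consistently wound and globally oriented outward by the sign of
  the enclosed volume; `surface_volume()` refuses open meshes and names the
  unmatched edges. Closed-mesh volumes are translation/rotation invariant to
  1e-9 relative; an inscribed triangulation undershoots a smooth surface by
  the chord deficit (about 1% at 30 x 30 on a sphere, quadratically
  vanishing), which the calibration absorbs.
* Shape columns are centered but never variance-scaled: all coordinates
  share physical units (mm), and per-column scaling would distort the
  geometry; the response is centered only, since scaling a univariate y
  merely rescales the coefficient vector.
* `simpls_fit()` follows de Jong's SIMPLS with an orthonormal loading basis
  for the cross-covariance deflation; with a univariate response the weight
  vector is the deflated cross-covariance itself. Coefficients for all
  1..M factor counts come from one pass (used by the cross-validation).
  Zero-variance responses, factor collapse (rank exhaustion) and out-of-range
  M are errors.
* Deflation uses the orthogonal-projector form; scoring new subjects applies
  the stored components sequentially (equivalent to direct projection for an
  orthonormal basis). Score variances are population (1/N) variances.
* Component angles are reported without absolute value: a PLS component's
  sign is pinned by its index, so 180 degrees is meaningful. PCA components
  instead fix sign by making the largest-magnitude loading positive.
* Cross-validation folds come from a seeded permutation, stratified by group
  label when provided; the generator restores the caller's RNG state so a
  fixed seed gives bitwise-reproducible cohorts without side effects.
* Degenerate inputs are errors with context (subject id, ring, step, index
  name) rather than NA propagation; a collapsed basal/apical cap in mesh
  closure is a warning because the volume is still defined.

## Problem sizes

The test-suite and acceptance computations run on scaled-down cohorts chosen
as the package's own verification sizes: n = 500 (one group) or ~500 mixed
for structural claims (zero correlation, orthonormality, recovery), n = 1000
per group for calibration means, 10-fold cross-validation at n = 150, and
10^6 Monte-Carlo samples for volume oracles. At the default 29 x 29 x 2 x 2
grid (P = 10,092) a full decomposition at n = 500 takes about two seconds.

## Limitations

Beyond the generator fidelity notes above: the package does not fit surface
models to images (inputs are already-corresponded point grids); the wall is
a fixed-offset shell, so wall volume is not conserved through the cycle;
infarct size and location are not modeled; and the extraction order affects
all components after the first — both the fixed reference order and greedy
variance ordering are provided, and neither is claimed canonical.
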