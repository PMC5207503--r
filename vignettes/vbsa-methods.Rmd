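---
title: "Estimating whole body surface area from a single depth-camera view"
author: "vbsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating whole body surface area from a single depth-camera view}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbsar)
```

## The problem and the model

The whole body surface area (WBSA) — the area of the skin — is a clinical
quantity (drug dosing, burn extent, indexing of cardiac measures) that is
hard to measure directly. A depth camera placed at azimuth $\theta$,
elevation $\phi$ and distance $D$ from a standing subject observes only
part of the skin; summing the areas of the observed surface gives the view
body surface area, $\mathrm{VBSA}(\theta,\phi)$. Across a population the
two are tied by a per-viewpoint linear model

$$\mathrm{WBSA} = c_1(\theta,\phi)\,\mathrm{VBSA}(\theta,\phi)
  + c_2\,\mathrm{Stature} + \dots + c_0(\theta,\phi),$$

fitted by ordinary least squares and judged by $k$-fold cross-validation.
`vbsar` provides the full virtual experiment: synthetic bodies with known
WBSA, a simulated depth sensor, the visibility ground truth, degradation
models, and the regression machinery. Everything downstream of the mesh is
measured in decimeters (areas in dm²), which puts adult WBSA near
100–300 dm².

The package follows the classic R modelling idiom for its statistical
core: `wbsa_model(formula, data)` returns a classed object with `print`,
`summary`, `coef`, `predict`, `residuals`, `simulate` and `plot` methods.
The geometry pipeline (bodies, camera, visibility) is a set of plain
functions orchestrated by `run_sweep()` and a thin command-line driver.

## Visibility ground truth via triangle identifiers

Each body is a triangle mesh with stable integer face identifiers. The
virtual camera traces one ray per pixel centre (pinhole model, intrinsic
matrix $K$ with focal length, pixel scales, skew and principal point) and
keeps only the nearest intersection, as a depth sensor does. Instead of
reconstructing a surface to measure it, the caster records *which*
triangle each ray hit; the deduplicated identifier list, looked up on the
original mesh, gives the ground-truth VBSA with no reconstruction noise:

$$\mathrm{VBSA} = \sum_{t \in \text{visible}} A_t, \qquad
  A_t = \tfrac12\,\lVert \mathbf u_t \times \mathbf v_t \rVert .$$

Two numerical regimes matter, and both are properties of the *counting*,
not of the intersection test:

* **Overestimation.** A partially visible triangle is counted in full, so
  coarse meshes inflate VBSA along silhouettes and occlusion boundaries.
  The remedy is flat midpoint subdivision (`subdivide()`, area-conserving
  by construction); sweeps subdivide once by default.
* **Undersampling.** A triangle whose projection is much smaller than a
  pixel may receive no ray at all; this deflates VBSA, worst for surfaces
  seen at grazing incidence (e.g. the rim of a sphere). The package's
  framing rule, $\text{maxStature} = 2\tan(\psi)\,D$ with $\psi$ half the
  vertical field of view, is therefore applied when configuring
  acquisitions: zooming the subject to fill the frame keeps the sampling
  density saturated. The interpretation of $\psi$ as the *half* field of
  view is the only one under which the frame-filling geometry closes.

These two biases pull in opposite directions; the test suite pins each one
against analytic oracles (a sphere's visible cap $2\pi R^2(1-R/D)$, exact
plane patches, and an exhaustive per-pixel intersection scan on small
meshes).

A consequence worth stating precisely: the similarity law "scaling the
body by $s$ scales every VBSA by $s^2$" holds *exactly* when the camera
distance is scaled together with the body (the rendered image is then
identical). With the camera fixed, perspective alone already breaks the
law at order size/$D$ — a sphere's visible cap is
$2\pi R^2(1 - R/D)$ — and sampling effects add more; the package tests
the joint-scaling form.

## The synthetic bodies

The humanoid is a parametric-primitive assembly, not a learned body model:
an egg-cross-section lathed trunk (front half deeper than the back, ring
centres shifted forward at belly and chest), capsule limbs, sphere head,
splayed feet, arms hanging at the sides bent slightly forward. Five macro
parameters drive it:

| parameter | meaning | default | range |
|---|---|---|---|
| `stature` | body height (cm); the mesh bounding box matches it | 175 | 120–220 in the random cohort |
| `girth` | cross-section scale, the weight proxy | 1 | 0.7 (emaciated) – 1.4 (obese) |
| `muscle_fat` | lean-to-fat balance; widens waist/belly, thickens limbs | 0.5 | 0–1 |
| `gender_shape` | feminine (0, wider hips/deeper bust) to masculine (1, wider shoulders) | 0.5 | 0–1 |
| `age` | years; grouping only (kid ≤ 15) | 30 | 6–80 |

Tape measurements (waist, hip, bust, underbust, neck, thigh, upper arm,
frontal chest) are computed analytically from the same cross-section
profiles that build the mesh, so they are exact for the geometry; weight
is a density proxy (0.985 kg/dm³ × analytic solid volume). The random
cohort samples every parameter *uniformly* — deliberately not normally —
so extreme builds, the hard cases for any WBSA formula, are
over-represented. The survey-style cohort fixes each base subject's
identity (stature, age, gender blend) and varies only girth and
muscle/fat on a near-square grid, producing fat and skinny versions of the
same individual (500 base × 25 variations = 12500 records). Stature
groups default to small ≤ 140 cm < normal ≤ 200 cm < big; the 140 cut is
configurable because 130 appears as an alternative convention.

What the generator reproduces, and what it does not: the qualitative
angle physics are faithful — the frontal view shows the maximum VBSA
(human trunks carry more surface in front, modelled by the egg
cross-section), the profile view the minimum, the rear slightly less than
the front, and occlusions grow toward oblique angles, so the VBSA
coefficient $c_1$ is smallest frontally and largest at $\theta = 90°$.
The bodies are, however, smooth unclothed primitives in one fixed pose:
no hair, skin folds, breathing motion or pose variation, and mesh WBSA
counts surfaces hidden inside joints. Numerical results (coefficients,
CV errors) therefore characterise the method, not any real population;
only the qualitative structure should be compared outside the package.
The arm pose matters more than one might expect: during development,
small protruding features (a nose-sized sphere) proved
*resolution-unstable* — at coarse sampling they remove more counted area
(by occluding their parent surface) than they add — which is why the
frontal surplus is modelled by smooth cross-section asymmetry instead.

## Sensor degradation

* **Axial noise** perturbs each depth by
  $\mathcal N\!\big(0, \sigma_z(z, \alpha)^2\big)$; the default
  $\sigma_z(z) = 0.0012 + 0.0019\,(z-0.4)^2$ m (depth in meters) follows
  the published empirical model for a structured-light consumer sensor.
  **Lateral noise** resamples each pixel's depth from a
  Gaussian-jittered source pixel (default 0.815 px). Noise is *off by
  default* and never touches the visibility ground truth — it corrupts
  the measured geometry, not which surface was seen.
* **Holes** emulate dropouts (IR interference, reflective skin): each
  visible triangle is removed independently with probability $p$ and its
  pixels blanked, so the surviving area is Binomial-thinned with mean
  $(1-p)\,\mathrm{VBSA}$.
* **Reconstruction** of the single view uses the organized grid directly:
  every 2×2 pixel quad with four finite depths and depth spread below a
  threshold (default 0.2 dm; prevents bridging across silhouette jumps)
  emits two triangles. Holes leave jagged unmeshed boundaries — exactly
  the error pathway that inflates area estimates in practice. An optional
  cleanup (`smooth_and_decimate()`) applies a 3×3 least-squares plane
  smoothing (equal, on the symmetric window, to the masked window mean)
  and voxel-grid thinning with nearest-kept-point mapping.

## Regression and validation choices

* OLS is solved by QR decomposition (via `lm`), not normal equations, for
  conditioning; rank-deficient designs fail loudly naming the collinear
  columns.
* Cross-validation uses $k = 10$ random near-equal folds from a recorded
  seed. MSPE is *pooled* over all held-out observations (so
  $\mathrm{RMSE} = \sqrt{\mathrm{MSPE}}$ exactly); fold-averaging was the
  other defensible convention and differs only at $O(1/n)$. MAPE is in
  percent.
* Spearman correlations use average ranks for ties; constant columns
  yield `NA` with a warning rather than a silent 0.
* Residual diagnostics provide the QQ table and a studentized
  Breusch–Pagan variance-trend test; heteroscedasticity is expected (and
  reproduced) at strongly oblique views, where overlapped limbs make the
  VBSA–WBSA relation fan out for large bodies.
* Grouped fits (sex, age group, stature class) skip groups smaller than
  $p + 2$ with a warning.

## Problem sizes and reproducibility

Default experiments are sized for a single CPU: populations of 60–200
subjects at mesh resolution ~4000 triangles (one subdivision round →
~16000 for ray casting), 640×480 acquisitions, and the 65-cell angle
grid; the qualitative angle checks use a reduced five-azimuth mini-sweep
{0°, 45°, 90°, 135°, 180°} at $\phi = 0$, which spans
front/oblique/profile/rear. Camera distance defaults to 43 dm (4.3 m),
the framing distance for the tallest subjects under the default optics;
below it, tall bodies crop out of frame and are flagged rather than
aborting a sweep. Every stochastic step (population draws, fold
assignment, noise, holes) takes an explicit seed and restores the
caller's RNG state, so sweeps are bitwise reproducible and resumable from
their per-cell CSV cache.

## Known limitations

Bodies are centrally-symmetric smooth primitives apart from the modelled
front/back asymmetry; visibility counting is resolution-dependent at
grazing incidence (quantified above) and ground-truth VBSA at a fixed
camera is therefore accurate to a few percent, not exact; the organized
reconstruction is intentionally simple (no hole filling, no normals) and
under-estimates area where acquisitions are degraded; and the weight
proxy ignores tissue composition, so Du Bois comparisons are indicative
only.
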