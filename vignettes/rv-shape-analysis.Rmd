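---
title: "Particle-based statistical shape analysis of the right ventricle in tricuspid regurgitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle-based statistical shape analysis of the right ventricle in tricuspid regurgitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvshape)
```

## The problem

Tricuspid regurgitation (TR) — retrograde flow from the right ventricle (RV)
into the right atrium through an incompetent tricuspid valve — is accompanied
by characteristic remodelling of the RV: outward protrusion of the free wall,
widening of the base and blunting of the apex. Because the RV is thin-walled
and geometrically complex, volumetric indices alone summarize this
remodelling poorly. Statistical shape modelling works instead with dense
*correspondence points* (particles): ordered surface landmarks placed so that
index $j$ occupies the anatomically analogous position on every subject, so
that point-wise statistics across a cohort become meaningful.

`rvshape` implements that analysis end to end: cohort generation →
preprocessing of binary segmentations → particle correspondence → PCA shape
space → TR classification → group shape statistics. Every stage is driven by
a synthetic cohort generator with known ground truth, so the full pipeline is
exercisable and testable without patient data.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure of a clinical study population of 54 subjects —
6 healthy volunteers, 27 comorbidity-matched controls (4 pulmonary
hypertension / 12 congestive heart failure / 11 other) and 21 TR patients
(3 / 9 / 9) — while remaining fully synthetic.

**Template.** The RV stand-in is a star-shaped radial surface
$r(\theta,\varphi)$ about the origin: a prolate ellipsoidal profile
(equatorial semi-axis 24 mm, polar 38 mm, i.e. a ~76 mm long chamber) with a
septally flattened, crescent-like cross-section and a mild azimuthal bend.
The bend and crescent remove all mirror symmetries so that rigid alignment is
well-posed. Star-shapedness buys two things: voxelization is an exact
point-in-surface test, and the shared $(\theta,\varphi)$ parameter grid *is*
the ground-truth correspondence — every sampled point lies exactly on the
surface at the same parameter location on every subject, which gives the
correspondence optimizer an exact oracle to be judged against.

**Group deformations.** Smooth parameter-space Gaussian bumps with unit peak,
scaled by per-group amplitudes in mm (so an amplitude *is* the maximum radial
displacement): TR shapes receive an outward free-wall bulge (default 5 mm),
apical blunting (3 mm) and basal widening (4 mm); comorbid controls an inward
mid-free-wall displacement (2.5 mm); the pulmonary-hypertension control
subgroup an additional circumferential mid-cavity narrowing of the same
amplitude ("streamlined" well-compensated RV). The patch definitions
(free wall, apex, base, mid-cavity) are fixed in template parameter
coordinates and exposed by `surface_patches()`, which is what the
localization tests check significance maps against. The study itself reports
only the *directions* of these changes, not magnitudes; the defaults are
plausible millimetre-scale choices fixed once, with the bulge five times the
shape-noise sd so that group structure is recoverable but not trivial.

**Subject noise.** Anatomical variation is smooth, so per-vertex white noise
would be both unrealistic and hostile to surface extraction. Subject-level
variation is a random radial field built from real orthonormal spherical
harmonics of degrees 1–6 with iid normal coefficients. By the addition
theorem the pointwise variance of such a field is constant over the sphere,
so the coefficient scale is set analytically to make the pointwise sd equal
`noise_sd` (default 1 mm) everywhere — which is what lets a test assert that
two subjects differ by an RMS of exactly $\sqrt2\,\texttt{noise\_sd}$.

**Rigid pose jitter.** Each subject additionally receives a small random
rigid rotation (per-axis sd 2°, stored as the surface's `pose`). This
emulates the rotational misalignment that survives a translation-only rigid
alignment of real segmentations. It is also statistically load-bearing: with
purely radial noise the per-point 3×3 coordinate covariance across subjects
is rank-1 (points move only along their ray), which makes the 3-dof
Hotelling $T^2$ F-test structurally conservative, with null rejection rates
an order of magnitude below nominal. Rotation jitter spans the tangent
plane at every point, restoring full-rank variation and a calibrated null
(asserted by the permutation-null calibration test in the suite). Shapes remain exactly star-shaped in their
canonical frame; voxelization maps voxel centers through the inverse pose.

**What the generator does not emulate** — and hence what passing tests do
*not* show about clinical data: MRI intensities and segmentation error,
anisotropic slice geometry beyond the resampling stage, papillary and
trabecular structure, multi-chamber context, and any real covariance between
comorbidity and shape. Synthetic group differences are smooth, single-peaked
and additive; clinical remodelling need not be.

## Preprocessing

Binary masks are nearest-neighbour resampled to isotropic spacing (default
1.5 mm, between the in-plane and through-plane resolutions typical of cine
MRI), padded to a common grid and translated so all foreground centroids
coincide: voxels move by whole steps and the sub-voxel remainder is absorbed
into each mask's origin, so centroids agree *exactly* in world coordinates
while dimensions and spacing stay identical. No size normalization is ever
applied — RV dilation is signal, not nuisance. Rotational (principal-axes)
alignment exists behind an opt-in flag with deterministic sign disambiguation
by third moments; it is off by default because the only stated constraint on
alignment is identical dimensions and centroids, and because the template's
two minor principal moments are nearly degenerate, making principal-axis
rotation about the long axis ill-posed.

Masks become exact signed Euclidean distance transforms
(Felzenszwalb–Huttenlocher, implemented in C++): negative inside, positive
outside, measured to the nearest opposite-phase voxel center minus half a
voxel (the voxel-face convention, fixed and asserted in tests). The zero
level set tracks the mask boundary and the gradient magnitude is ≈1 away
from the medial axis, which is what the particle system's surface constraint
relies on.

## Particle correspondence

`optimize_particles()` distributes $M$ ordered particles (default 512) on
every subject's zero level set by gradient descent on

$$\alpha\,\underbrace{\log\det\!\big(\mathrm{cov}(z_1,\dots,z_K)+\varepsilon I\big)}_{\text{ensemble term}}
\;+\;(1-\alpha)\,\underbrace{\sum_k\sum_i \log\!\sum_{j\ne i}
e^{-\|p_i-p_j\|^2/2\sigma_i^2}}_{\text{sampling term}}$$

where $z_k$ is subject $k$'s flattened $3M$-vector of particle coordinates.
The sampling term is the negative particle entropy per shape — minimizing it
spreads particles uniformly — and the ensemble term is the regularized
log-determinant of the cross-subject covariance, whose minimization makes
index $j$ occupy the same anatomical spot everywhere. Since $K \ll 3M$ the
covariance is rank-deficient by construction; the ridge is
$\varepsilon = 10^{-2}\,\mathrm{mm}^2$ and the log-determinant is evaluated
in the $K\times K$ dual. Particles grow by a $1\to2\to\dots\to M$ splitting
schedule: each split duplicates every particle with a small offset drawn
once from the seeded generator and *shared across subjects* (applied in each
subject's tangent plane, because a normal offset would be annihilated by the
surface projection), which is what guarantees that identical shapes receive
identical landmarks. Steps use backtracking halving and are rejected if the
objective would increase, so the objective trace is non-increasing; the
whole run is deterministic given the seed.

Three choices here were forced by observed failure modes, and differ from
the obvious textbook setup:

* **Per-particle adaptive bandwidths.** With a single stage-global kernel
  width $\sigma$, the repulsive force between a newly split, near-coincident
  pair scales as $d/\sigma^2$ and vanishes as $d\to0$; the pairs re-merge
  under the ambient density flow and the configuration degenerates into
  coincident clusters. Each particle's bandwidth is therefore its current nearest-neighbour
  distance clamped to $[\text{spacing}/2,\ \sigma_\text{stage}]$, frozen
  within an iteration; close pairs then always feel a separation force
  comparable to the global gradient scale.
* **Separate normalization of the two gradient families.** The log-det
  gradient scales like the *inverse* of the de-correspondence magnitude: it
  saturates exactly when correspondence is being lost. Jointly normalized,
  the sampling gradient drowns it and cross-subject correspondence never
  forms. Each family is
  normalized to unit maximum step first, then mixed by $\alpha$.
* **$\alpha = 0.8$.** With the families on equal footing ($\alpha=0.5$) the
  slow stochastic drift that per-shape repulsion dynamics induce on
  similar-but-not-identical surfaces still beats the restoring force, and
  per-index cross-subject variance grows stage by stage; 0.8 holds it at
  the noise floor (the ground-truth trajectory-error oracle in the suite
  checks the result). $\alpha$ still ramps from 0 over the first stage so
  early sampling is unconstrained.

The first particle is seeded by projecting a common exterior point on the
+x axis, not the centroid: at the centroid the distance-field gradient is
medial-axis noise and sends each subject's first particle to a different
anatomical location, poisoning everything downstream.

The ground-truth bypass `attach_ground_truth()` subsamples the generator's
parameter grid by deterministic farthest-point selection (greedy, started at
the apex pole sample) and uses the same indices on all subjects. It is the
default correspondence source in the orchestrated pipeline so the
statistical stages can be validated independently of optimizer quality; the
optimizer path is exercised by its own oracles (identical-shape variance,
sphere uniformity, ground-truth trajectory error < 2× spacing on a low-noise
cohort).

## Shape space and classification

PCA is fit on the full cohort (all groups jointly, matching the workflow
order of model-then-split; a train-only fit is available via the stage
functions), by SVD of the centered $K\times3M$ matrix, eigenvalues
normalized by $K-1$, mode signs fixed so each mode's largest-magnitude
component is positive. Loadings passed to classification are truncated to
the modes explaining 99% of variance — keeping numerically-zero-variance
trailing modes would otherwise hand the sparse selector spurious perfect
separators.

The classification stage mirrors a standard imbalanced-learning pipeline:
stratified 80/20 split (train size $\lfloor0.8n\rfloor$, allocated across
classes by largest remainder); Borderline-SMOTE balancing of the two
minority groups (TR patients and healthy volunteers) up to the comorbid
control count, with the borderline rule "at least half but not all of the
$k{=}5$ nearest neighbours belong to other groups" and synthetic samples
drawn as exact convex combinations of a borderline point and a within-group
neighbour (if a minority class has no borderline member — common when
synthetic groups separate cleanly — all its members seed the upsampling,
with a warning); lasso stability selection — 1000 intercept-free L1 fits of
the binary label on random 80% subsets, regularization chosen per fit by
stratified 3-fold CV over a 100-value path, without predictor
standardization (standardization inflates near-zero-variance modes into
spurious selections), a mode's *dominance* being the fraction of fits in
which its weight is non-zero; the top four dominant modes then feed a
ridge-penalized logistic model whose penalty is chosen by 3-fold CV on AUC.
Because AUC is a ranking criterion it plateaus at its maximum on separable
data, and the conventional tie-break (strongest penalty) degenerates to
prior-probability predictions; among models with equal CV score the least
penalized is used. Metrics are computed from the confusion matrix at
threshold 0.5 by the standard formulas, the ROC by threshold sweep, AUC by
the trapezoid rule.

The subset size of the stability-selection resamples is not pinned down by
the source workflow; 80% without replacement is the common
stability-selection default and is configurable.

## Group statistics

The linear discrimination of variation (LDV) projects every subject's
centered shape vector onto the difference of two group mean shapes,
$d = \mu_B - \mu_A$, then maps the two group-mean projections affinely to
$-1$ (the TR-containing group) and $+1$. Centering shifts all raw
projections by one constant that the affine map absorbs, so scores are
identical either way; the map is strictly increasing since its span is
$\|d\|^2>0$. A Gaussian is moment-matched to each group's normalized scores.
`overlap_fraction()` reports the fraction of subjects inside the
intersection of the two groups' score ranges — the notion of "overlapping
region" is under-specified in the source analysis, so range intersection is
an explicit, documented interpretation and no clinical percentage is claimed
to be reproduced.

Per-point significance maps use the two-sample Hotelling $T^2$ on each
correspondence point's 3D coordinates, pooled covariance ridge-regularized
by $10^{-6}$ mm² (a point whose covariance is singular even then is flagged
with $p=1$), p-values from the $F(3,\,n_1{+}n_2{-}4)$ transform (a
label-permutation option exists for very small groups), and
Benjamini–Hochberg step-up FDR adjustment at 0.05. BH was chosen as the
standard, reproducible step-up estimator; the FDR-validity test reads its
50-shuffle mean false-discovery proportion through an exact one-sided
binomial test against rate 0.05, since at 50 shuffles the raw mean has
granularity 0.02 and would flag a correctly controlled procedure in about
one run in five.

## Problem sizes and numerical choices

The validation suites run at reduced, stated sizes chosen to exercise every
code path: correspondence oracles at $M=64$–$128$ particles on 48³–64³ mm
grids with 2–6 subjects; calibration and localization at $M=128$ with 20
subjects per arm; classifier recovery over 20 cohort seeds at $M=128$ with
100 stability-selection repeats; feature-selection stability at 200 repeats
over 20 seeds. The full defaults (512 particles, 1000 repeats, 96² parameter
grid) are what `pipeline_config()` ships with. Other numerical fixities:
surface tolerance for particles is half the voxel spacing; projection is a
damped Newton iteration on the interpolated field (step $-D\,g/\|g\|$,
bounded near the medial axis, iterates clamped to the grid interior, at most
20 sweeps); voxelization declares a voxel foreground iff its center is
strictly inside the surface, with odd default grid dimensions so a voxel
center sits at the shape center; ties in top-mode selection break toward the
lower mode index.

## Known limitations

The correspondence optimizer is a compact reimplementation of the
particle-based idea, not of any specific software release; its iteration
counts, bandwidth schedule and $\alpha$ are package choices documented
above, and no claim is made that they match any published tool's internal
configuration. Within-shape uniformity degrades somewhat at high $\alpha$
(clustered but well-corresponded particles); the sampling-only setting
($\alpha=0$) recovers uniform coverage, and the uniformity oracles run in
that regime. The LDV overlap fraction and the SMOTE no-borderline fallback
are explicit interpretations of under-specified steps. The F-based
per-point test assumes per-point Gaussian coordinates, which the generator
satisfies by construction; heavy-tailed clinical variation would call for
the permutation option.
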