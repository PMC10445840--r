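---
title: "Spatio-temporal fetal brain atlas construction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal fetal brain atlas construction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbatlas)
```

## The problem

Fetuses with spina bifida aperta (SBA) show strongly abnormal brain anatomy
— enlarged lateral ventricles in particular — so atlases of the *normal*
developing brain are a poor spatial prior for registering or segmenting
their MRI.  `sbatlas` builds a *spatio-temporal* atlas from a cohort of
reconstructed 3D fetal brain MRIs: a collection of average volumes indexed
by gestational week and by fetal-surgery status, each with a brain mask,
averaged tissue probability maps, a tissue parcellation and a set of
consensus anatomical landmarks.

The pipeline has four stages, all exposed as ordinary functions:

1. **Grouping** (`build_groups()`, `augment_group()`): sessions are binned
   into overlapping (week, status) groups with a truncated Gaussian
   temporal weight.
2. **Initialization** (`initialize_atlas()`): a weighted generalized
   Procrustes (WGP) alignment of the anatomical landmarks — image intensity
   is deliberately not used — followed by time-weighted, mirror-symmetric
   averaging of the normalized intensities and probability maps.
3. **Refinement** (`refine_atlas()`): non-linear registration of every
   member to the current atlas (LNCC + landmark data term, bending + linear
   energy regularization on a cubic B-spline lattice) and re-averaging,
   iterated.
4. **Parcellation / evaluation** (`argmax_parcellation()`,
   `segment_with_atlas()`, `reliability_analysis()`).

## Temporal model

The weight of session $i$ in the group with target age $GA_t$ is

$$w_i = \frac{1}{\sqrt{2\pi}\,\sigma}
  \exp\!\Big(-\tfrac12\big(\tfrac{GA_i - GA_t}{\sigma}\big)^2\Big),
  \qquad \sigma = 3\ \text{days},$$

truncated to zero when $|GA_i - GA_t| > 3\sigma = 9$ days, which is also
the group-inclusion window.  A group is kept only if it has at least 3
members before flip augmentation and contains members both strictly above
and strictly below the target age.  A member exactly at the target age
counts as neither (the strict reading of "higher and lower"); with
integer-day ages and whole-week targets the boundary case is rare and the
strict rule is the conservative one.  Gestational age is stored as integer
days throughout (weeks+days arithmetic is exact), and week-labelled groups
sit at $7\cdot\text{week}$ days.

## The landmark registry

Eleven protocol landmarks are registered (`landmark_registry()`): the
anterior ventricle horns (RALV/LALV), the posterior tectum plate (PTP,
midline), the cerebellar–brainstem junctions (LCB/RCB), the deep grey
matter borders at the foramen of Monro (LFOM/RFOM), and four deep-grey
borders at the cavum septi pellucidi lines (L/RACSP, L/RPCSP).  The four
CSP landmarks are kept in the registry with `retained = FALSE` — they are
part of the annotation protocol and of reliability reporting — but only the
seven retained landmarks enter atlas construction.  Label-map landmark
files use the registry row number as the voxel label (1–7 retained, 8–11
CSP); annotations may cover several voxels, and the physical centroid is
taken.

## Weighted generalized Procrustes with missing landmarks

Each sample $i$ is aligned by an anisotropic scaling $M_i =
\mathrm{diag}(s_i)$ plus translation $t_i$ (no rotation: volumes are
assumed already in a standard orientation).  With per-landmark weights
$w_{i,k} \ge 0$ (the temporal weight, or 0 for a missing annotation), the
problem is

$$\min_{\{M_i, t_i\},\, \{g_k\}} \tfrac12 \sum_{i=1}^n \sum_{k=1}^K
  w_{i,k}\, \| M_i x_{i,k} + t_i - g_k \|^2$$

subject to two constraints on the consensus $g$: its barycenter and its
size (mean squared deviation about the barycenter) must equal those of the
weighted raw-landmark means $\bar x_k$.  Without the constraints the
problem collapses to a point.

`solve_wgp()` alternates two **exact** block minimizations, so the
objective trace is non-increasing by construction:

* *Transforms.*  Per sample and per axis the problem separates into a 1-D
  weighted regression with closed form.  Axes with fewer than two
  positively weighted landmarks, or without coordinate spread, fall back to
  scale 1 and a weighted-mean translation; fitted scales are floored at a
  tiny positive value.
* *Consensus.*  Minimizing over $g$ at fixed transforms under both
  constraints is a quadratic with one linear and one spherical constraint.
  We solve it exactly via the associated secular equation in the Lagrange
  multiplier (including the hard case), rather than by the heuristic
  "translate, then rescale" projection: the heuristic is only the exact
  minimizer when all per-landmark total weights are equal, and with unequal
  weights it can break the monotonicity of the alternation.

**Global versus structure-preserving solutions.**  The objective is jointly
convex in transforms and consensus, and the optimal transforms are linear
in $g$; eliminating them leaves one quadratic form per axis, whose
constrained minimum is computable exactly (a trust-region subproblem).
With `global_init = TRUE` (default) the alternation starts there and
reaches the constrained global optimum in a couple of sweeps — this is the
mode benchmarked against an independent multi-restart optimizer in the test
suite.  The global optimum of the *problem*, however, has a caveat: only
the overall size of the consensus is constrained, and scale factors may
approach zero, so on noisy instances the global solution can collapse the
consensus along one or two axes (each sample's cheap axes are shrunk to a
point).  That configuration is anatomically meaningless, which is why
`initialize_atlas()` calls `solve_wgp(..., global_init = FALSE)`: the
classical alternation from identity transforms and feasible consensus
converges to the structure-preserving local solution.  On the low-noise,
near-matchable landmark sets that groups of real or phantom brains produce,
the two coincide (the aligned solution is globally optimal when residual
mismatch is small), so the distinction only matters for adversarially noisy
configurations.

## Intensity normalization and symmetric averaging

Before averaging, each volume is linearly mapped so its in-mask mean and
standard deviation are exactly 2000 and 500 (`normalize_intensity()`),
matching the intensity profile convention of spatio-temporal fetal atlases.
The group average is

$$I_{\text{avg}} = \frac{1}{2N} \sum_{i=1}^N \tilde w_i\,(I_i + S(I_i)),$$

where $S$ mirrors a volume about the central sagittal plane of its grid.
The weights are renormalized to $\sum_i \tilde w_i = N$, making the
operator a convex combination of symmetrized volumes — without this the
atlas intensity would scale with group size, contradicting the fixed
2000/500 profile.  The output is *exactly* $S$-symmetric in floating point
(each voxel pairs with its mirror through a commutative sum), which the
tests assert voxelwise.  Probability maps are averaged with the same
operator per class (all 8 tissue classes are bilaterally self-symmetric),
and convexity preserves the voxelwise class-sum of 1.  The parcellation
takes the class of maximal probability, ties resolving to the lowest class
index for determinism.

The atlas grid is voxelized at the input spacing over the bounding box of
the Procrustes-transformed masks, padded by 5 voxels, and centred along x
on the consensus barycenter so that the mirror plane of the averaging
operator coincides with the consensus mid-sagittal plane.  Consensus
landmarks of mirror pairs are exactly symmetrized about that plane
(augmented groups make them symmetric up to numerical error; the residual
is removed).

## Non-linear registration

The refinement and segmentation registrations minimize

$$-\alpha_{LNCC}\,\mathrm{LNCC}(I_f, I_m \circ \phi)
  + \alpha_{LMKS} \sum_{k\in\Omega} \|\phi(x_k^f) - x_k^m\|^2
  + \alpha_{BE}\,\mathrm{BE}(\phi) + \alpha_{LE}\,\mathrm{LE}(\phi)$$

over a cubic B-spline displacement lattice (3 mm control spacing composed
with an affine initialization), with $\alpha_{BE} = 0.1$, $\alpha_{LE} =
0.3$, $\alpha_{LMKS} = 0.001$ and $\alpha_{LNCC} = (1 - \alpha_{LMKS})(1 -
\alpha_{BE} - \alpha_{LE}) = 0.5994$, LNCC window sd 6 mm, and a 3-level
image pyramid (x4/x2/x1 with control spacing halving per level).  Those
defaults are the tuned values of the published method and live in
`pipeline_config()`.

Numerical choices that were open:

* **LNCC aggregate**: the mean over in-mask voxels of the squared local
  correlation coefficient, with local moments from a boundary-renormalized
  Gaussian window and a variance floor of $10^{-6}$; $\rho^2$ is
  sign-insensitive and invariant to positive affine intensity maps.
* **Energies**: evaluated on the control lattice with central finite
  differences restricted to interior nodes — bending is the mean squared
  second derivative (with doubled mixed terms), linear is the mean squared
  Frobenius norm of the symmetric Jacobian part, so translations cost
  nothing and infinitesimal rotations are free for the linear term.
* **Optimizer**: steepest descent with backtracking line search and
  analytic gradients for every term (the LNCC gradient is propagated
  through the moment smoothing and chained through the warped image's
  spatial gradient onto the lattice).  A step is accepted only if the cost
  decreases, so per-level cost traces are monotone; the whole procedure is
  deterministic.
* **Affine initialization**: per-axis least squares on shared landmarks
  when at least 4 are present, otherwise matching of brain-mask moments.
  (A block-matching initializer would be a means to the same end; it is not
  part of the method's contribution and is not re-implemented.)
* **Transform direction**: subject→atlas, with atlas rasters pulled back
  into subject space, so label propagation needs no numerical inversion.
  Refinement needs member images on the *atlas* grid, so there the atlas
  frame is registered to each member (fixed = current atlas) and member
  rasters are pulled back — the same objective family with the roles
  swapped, again avoiding inversion.  Consensus landmarks are kept fixed
  across refinement iterations (2 by default; the count is configurable and
  the member-to-atlas LNCC trace is logged in the provenance).

No claim of numerical equivalence with any particular registration backend
is made; the objective, parameters and pyramid are as published, the
optimizer is this package's own.

## Atlas-based segmentation and reliability analysis

`segment_with_atlas()` picks the time point with matching surgery status
and nearest target age (ties to the younger), registers the subject
*without* the landmark term (segmentation-time subjects are not annotated),
propagates the parcellation with nearest-neighbour interpolation, and
merges the corpus callosum into white matter, yielding 7 evaluated tissue
classes plus whole brain, scored by Dice and HD95 (boundary voxels by
6-connectivity; directed 95th-percentile distances, maximized over both
directions).

`reliability_analysis()` follows the published intra-rater protocol: per
landmark, Euclidean distances between paired sessions are fitted by a
Gaussian (the model is applied to non-negative distances exactly as
specified, so it can put mass below zero — a documented modelling
assumption, not a bug), percentiles are $\mu + z_q \sigma$, and the
agreement probability $P(d \le r)$ feeds the category thresholds
(≥95% Excellent, ≥80% Good, ≥75% Satisfactory, else Poor; boundaries
inclusive).  The cube predicate ("within the 3×3×3 voxel cube") and the
Gaussian-distance model are not mutually consistent, so the agreement
radius is an explicit parameter, defaulting to the circumscribed-sphere
radius $\sqrt{3}\cdot$ voxel (1.386 mm at 0.8 mm voxels); the empirical
cube-agreement rate is reported alongside.  The missing ratio counts a
volume as missing when the landmark is absent in *either* session.

## The phantom generator

`make_phantom()` builds grid-centred, bilaterally symmetric brain-like
volumes from nested ellipsoids covering the 8 tissue classes, with a linear
growth model (overall scale 1.0 at 21 weeks to 1.8 at 34 weeks), a
ventricle-enlargement factor (`severity`, scaling ventricle semi-axes by
$1+\text{severity}$ — the SBA ventriculomegaly surrogate), per-tissue mean
intensities with Gaussian noise (sd 20 by default) and an optional
polynomial bias field.  All 11 landmarks sit at analytic loci (ventricle
tips, deep-grey poles, cerebellar–brainstem junctions, tectum pole), so
every alignment step has a known ground truth; `perturb_phantom()` applies
a known anisotropic scaling + translation + invertible band-limited warp
and returns the exact transform, and `make_cohort()` emulates a mixed
operated/non-operated longitudinal cohort (operated sessions only after the
25-week surgery age).

What the phantoms deliberately do **not** model: cortical folding and
gyrification, acquisition physics (bias beyond a low-order polynomial,
motion, partial volume), true SBA posterior-fossa anatomy, or rater noise
in landmark placement.  Passing tests therefore demonstrate the
correctness of the machinery (alignment recovery, symmetry, weighting,
propagation) under known ground truth — not clinical-grade accuracy on real
fetal MRI.

## Problem sizes and defaults used in the tests

The test-suite phantoms use 48³ voxels at 1.0 mm (registration and
pipeline fixtures) and 36³ at 1.4 mm (orchestration fixtures); the
generator default is 64³ at 0.8 mm, matching the working resolution of the
published pipeline.  Procrustes oracle comparisons run 20 random instances
with $n \le 4$, $K = 7$ and 30% missing landmarks against a 20-restart
quasi-Newton optimizer on the constraint manifold.  Registration recovery
uses 5 seeds with ≤3 mm warps on 48³ grids.  These sizes were chosen so
the full suite exercises every stage end to end at desk scale.

## Known limitations

* The FFD has no diffeomorphic guarantee; large requested warps can fold
  (the phantom perturbation refuses warps near non-invertibility, the
  registration relies on the bending/linear penalties).
* Groups at the extremes of the age range can fail the bracketing rule and
  are dropped rather than extrapolated.
* The WGP global optimum can be anatomically degenerate on high-noise
  landmark sets (see above); the pipeline uses the identity-initialized
  mode and the solver exposes both.
* Intensity averaging assumes successful normalization; volumes with
  constant in-mask intensity are rejected rather than guessed at.
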