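---
title: "Voxel-based dosimetric analysis in template space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based dosimetric analysis in template space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(doseatlas)
```

# The problem

Radiotherapy for nasopharyngeal carcinoma (NPC) delivers high doses close
to the brain; which normal-tissue regions absorb how much dose depends on
the delivery technique (static-field IMRT versus rotational VMAT).
Conventional organ-level dose-volume summaries hide the spatial pattern.
The alternative implemented here is a voxel-based analysis: every
subject's planning CT and its co-registered 3D dose distribution are
spatially normalized into one template (MNI-like) coordinate system, so
that each template voxel carries one dose value per subject, and the two
technique groups are compared voxel-by-voxel with a permutation test.

`doseatlas` implements the full pipeline: NIfTI volume handling,
synchronized spatial normalization, group dose mapping by dose sub-range,
a voxel-wise two-sample GLM with age and gender covariates, threshold-free
cluster enhancement (TFCE) with permutation family-wise-error (FWE)
inference, and atlas-labelled cluster reports. Because the patient data
behind such studies are private, the package ships a digital head-phantom
cohort generator with exact ground truth, and its test suite validates
every stage against that ground truth.

# Synchronized spatial normalization

Planning CT and dose are, by construction of the treatment planning
system, on the same grid, so a single transform chain estimated from the
CT can be applied to both ("synchronization"). The chain is

1. **Crop** — the head is segmented on CT (largest connected component
   above -500 HU), the bounding box padded by 10 mm except inferiorly
   (removing neck signal), and both volumes cropped with affines updated
   so world coordinates are preserved.
2. **Rigid** (6 parameters) — automatic SSD minimization replaces the
   manual anterior/posterior-commissure alignment of interactive
   workflows, for reproducibility. Multiresolution (downsampling factors
   4/2/1) Nelder–Mead with a finite-difference quasi-Newton polish at the
   finest level. Nelder–Mead is the gradient-free direct search available
   in base R; any direct-search method satisfies the same contract.
3. **Affine** (12 parameters: rotations, translations, log-scales,
   shears), initialized from the rigid fit; same optimizer.
4. **Nonlinear** — a smooth displacement field parameterized by
   low-frequency 3D DCT basis functions (~24 mm basis spacing),
   estimated by minimizing masked SSD on intensity-normalized,
   Gaussian-presmoothed volumes (8/4/2 mm schedule) plus a
   membrane-energy penalty, via Levenberg–Marquardt-damped Gauss–Newton
   with analytic gradients. This is the classical basis-function
   normalization of statistical parametric mapping, i.e. the algorithm
   family of the software used in the studies this pipeline emulates.

The chain is applied in a *single* composed resampling pass
(`apply_chain()`): CT with Catmull–Rom cubic interpolation, dose with
trilinear, masks/atlases with nearest-neighbour. Dose is moved without
Jacobian scaling: absorbed dose is a point quantity in Gy, not a density.

## Why basis functions and not greedy demons

A demons-style greedy scheme (per-voxel SSD-gradient updates with
Gaussian regularization) was implemented first and failed its own
validation: on the phantom it could not recover a known 4 mm-RMS smooth
field to better than ~2–4 mm RMS. Diagnosis, in order of discovery:
out-of-field intensity fill leaking into the objective at the grid
border; greedy per-voxel updates drifting in weakly textured regions;
and, decisively, a *model* bias — initializing at the true field, the
optimizer walked away from it to a lower SSD, because one-sided trilinear
resampling imprints a position-dependent blur that the objective can
exploit. Three changes fixed this:

* a low-dimensional smooth parameterization (DCT basis) optimized
  globally by Gauss–Newton instead of greedy local updates;
* Catmull–Rom (cubic) resampling inside the objective, whose response is
  far less position-dependent than trilinear;
* excluding from the SSD all voxels whose sample points fall outside (or
  within 2 voxels of) the moving volume's field of view.

With these, the known-field recovery error is ~1 mm RMS, within the
1.5 mm acceptance tolerance, and end-to-end dose mapping agrees with the
generator's template-space ground truth to ~1 Gy RMS inside the brain
mask (tolerance 2 Gy).

## Numerical choices

* Template grid: 91×109×91 voxels, 2 mm isotropic, origin
  (-90, -126, -72) mm — the standard MNI 2 mm bounding box. Reported
  coordinates are world mm (RAS) in template space.
* Out-of-field values: 0 for dose, -1024 HU (air) for CT.
* Registration objective traces are non-increasing by construction
  (only steps that decrease the — for the nonlinear stage, regularized —
  objective are accepted); a failed line search / failed damping sweep
  stops the stage.
* Membrane penalty weight `lambda = 0.05` on z-scored intensities;
  exposed, as are the basis spacing and presmoothing schedule.

# The dose model of the phantom cohort

`make_template_phantom()` builds a CT-like head: soft-tissue ellipsoid
(40 HU) with a skull shell (700 HU), brain (30 HU), ventricle analogues
(5 HU), air outside, plus a seeded multi-scale texture (RMS 40 HU at
24/12/6 mm scales) inside the brain. The texture stands in for the
soft-tissue structure (sulci, nuclei, gray/white contrast) that makes
intensity-based registration well-posed in real head CT; a featureless
phantom would make the deformable problem unidentifiable and would
validate nothing.

`sample_subject()` warps the template by a random rigid offset (≤ 8 mm,
≤ 5° per axis by default; bounds configurable up to the 15 mm / 10°
operating range) composed with a random smooth displacement field
(Gaussian-smoothed noise, correlation length 30 mm, RMS 4 mm) — the
scale of residual inter-subject anatomical variability after affine
alignment — plus 5 HU acquisition noise. Subjects are synthesized with
cubic interpolation: trilinear would imprint a field-correlated blur
pattern, an artifact of discrete generation that real acquisitions do
not have. The exact generating chain is stored, giving every
registration test an oracle.

`simulate_dose()` models the delivered dose as

* prescription dose (drawn per subject from Normal(70.4, 1.2) Gy
  truncated to [66.9, 74.2] Gy, the reference cohort's range) on a
  nasopharynx-analogue target ellipsoid inferior–anterior to the brain,
  with T stage scaling the target radius;
* exponential falloff `Rx * exp(-d / 25 mm)` with distance `d` from the
  target surface, placing temporal/limbic-analogue voxels near the
  target above 50 Gy;
* a technique term: a Gaussian lobe of amplitude `effect_size` (Gy)
  shifted anteriorly for IMRT and posteriorly for VMAT — group
  differences are *injected*, not emergent, so the analysis can be
  scored against exact truth. The default amplitude is 0 (exchangeable
  groups), the configuration under which FWE calibration is tested;
* a smooth inter-subject noise field (RMS 2 Gy, correlation 10 mm),
  tapered to zero inside the target so that coverage is exact: at least
  95% of target voxels receive the prescription, the planning goal the
  generator must satisfy. The 2 Gy RMS is a realistic scale of
  inter-patient plan variability in brain tissue; no published noise
  model exists for this quantity.
* Dose is clipped at 0 and zeroed outside the head support. Ages have no
  effect on dose by default; an `age_dose_slope` exists to exercise
  covariate adjustment.

What a green test does *not* establish: the phantom has no plan-optimizer
physics (no beam/arc geometry, no OAR trade-offs), its anatomy is a
coarse ellipsoid model, and the injected technique difference is a
controlled additive lobe rather than an emergent fluence pattern.
Conclusions about real IMRT/VMAT differences require real cohorts; the
phantom validates the *pipeline*, not the clinical claim.

# Voxel-wise inference

At every brain-mask voxel an ordinary-least-squares GLM is fitted with
intercept, group indicator (IMRT = 1), centred age, and gender
(male = 1); the group contrast gives
`t = c'b / sqrt(sigma^2 c'(X'X)^-1 c)` with `df = n - rank(X)`. With no
covariates this reduces *exactly* to the pooled-variance two-sample t
(verified to 1e-10 in the tests). Zero-variance voxels get t = 0 and are
flagged.

TFCE integrates cluster extent and height over all thresholds:
`TFCE(v) = sum_h e_v(h)^E h^H dh` with the volumetric defaults E = 0.5,
H = 2, 26-connectivity, and `dh = h_max / 100`. The implementation is an
incremental union-find over a single descending threshold sweep and is
tested for exact equality against an explicit threshold-loop brute force.

FWE inference uses Freedman–Lane residual permutation: the reduced
(covariate-only) model is fitted, its residuals are permuted with a
seeded RNG, the full model is refitted, and the mask-wide maximum TFCE
is recorded per tail; the identity permutation is always included, so
`fwe_p = (1 + #[null >= tfce]) / (1 + n_perm)` with minimum attainable
p of `1/(1 + n_perm)`.

**Tails.** The published tables report the two directions separately at
"FWE p < 0.05". Testing each direction against its own max-null at
alpha = 0.05 gives a family-wise any-voxel rate near 2 alpha (~9% —
measured, not hypothetical), which contradicts the 5% family-wise claim
such analyses make. The package therefore defaults to a single
two-sided null — the permutation distribution of the maximum TFCE over
*both* tails on a common threshold grid — which controls the family rate
at alpha while still reporting each direction's significant voxels
separately. `tails = "separate"` switches to the liberal per-tail
convention.

# Dose maps, sub-ranges and ROIs

Group mean dose maps are voxel-wise arithmetic means inside the brain
mask. Dose sub-ranges follow the display convention 1.0–1.5, 1.5–10,
10–30, 30–50, > 50 Gy: half-open bins `[lo, hi)`, the last bin strictly
`> 50`, voxels under the 1.0 Gy display floor uncounted. Counts plus the
below-floor count always partition the brain-mask voxels exactly (a
tested invariant).

High-dose regions of interest are built as
(mean dose > 50 Gy) ∩ atlas lobe ∩ hemisphere, with laterality split at
world x = 0 (the template is midline-centred). Per-subject ROI mean
doses feed a two-sided two-sample t-test per ROI; covariate-free by
default (the source analyses do not state covariate use at ROI level),
with `use_glm = TRUE` for an age/gender-adjusted linear model.

The bundled phantom atlas has 12 coarse anatomically-placed analogue
regions (temporal, limbic, frontal, occipital, parietal, anterior and
posterior cerebellum, brainstem, sub-lobar, ventricles); real labelled
atlases are accepted via `read_atlas()` (label NIfTI + TSV table) but
not bundled. Cluster reports list region, voxel count, signed peak t and
the world coordinate of the peak (ties broken by the first voxel in
scan order, since a single coordinate must be reported).

# Known limitations

* SSD is a mono-modal objective; cross-modality registration is out of
  scope.
* The deformation model is low-frequency (~24 mm basis spacing);
  fine-scale anatomical differences are neither modelled by the phantom
  nor recoverable from low-contrast CT.
* No topology guarantees (diffeomorphism) and no inverse-consistent
  registration; `invert_chain()` uses fixed-point inversion, accurate
  for the smooth fields produced here.
* The two acceptance-grade quantities that can be recomputed at desk
  scale are properties of the method (FWE calibration, target coverage);
  the published cohort-level voxel counts and cluster tables derive from
  803 private scans and are not reproducible here.
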