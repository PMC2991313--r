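---
title: "Methods: 3D reconstruction and voxel-wise statistics for autoradiographic brain sections"
author: "autorad3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D reconstruction and voxel-wise statistics for autoradiographic brain sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Quantitative ^14^C-2-deoxyglucose (2DG) autoradiography maps cerebral
glucose metabolism at film resolution, but each animal yields only a pile
of independent 2D sections: the 3D spatial consistency of the brain is
lost at the cryostat. Region-of-interest densitometry recovers numbers
from those sections at the cost of an a-priori anatomical hypothesis and
considerable operator effort. `autorad3d` implements the alternative:
rebuild each brain in 3D, carry every brain into one reference space, and
test group differences voxel by voxel, with multiple-testing control.

The chain has five steps, each exposed as package functions and driven
end-to-end by `run_pipeline()`:

1. **Cleaning** (`clean_subject`) — Otsu's threshold separates tissue from
   film background; a binary opening detaches dust and overlapping
   sections; the largest 8-connected component is kept.
2. **Calibration** (`fit_calibration`, `apply_calibration`) — gray levels
   become activities (nCi/g) through a natural cubic spline fitted to the
   co-exposed ^14^C standards. One film per animal means one calibration
   per animal.
3. **Reconstruction** (`stack_sections`, `align_stack_center_out`) —
   sections are stacked along z and realigned sequentially from the two
   central sections outward, each section rigidly registered (3 in-plane
   DOF) to its already-aligned inner neighbour by maximizing normalized
   cross-correlation (NCC), first on ×4-downsampled sections, then refined
   at full resolution.
4. **Normalization** (`register_affine_3d`, `register_bspline_3d`,
   `warp_volume`) — each reconstructed volume is warped onto a smoothed
   reference subject (FWHM = 3 × voxel) by a 12-DOF affine then a cubic
   B-spline free-form deformation, both multi-resolution with an NCC
   metric.
5. **Statistics** (`run_stats`) — subject volumes are globally scaled,
   smoothed (FWHM = 3 × voxel), and compared with a pooled two-sample t
   per voxel; one-sided p-maps for both directions, Benjamini–Hochberg
   FDR and family-wise error control (Bonferroni or permutation max-T),
   then 26-connected cluster-size filtering.

Because real film data cannot ship with a package, a first-class phantom
generator (`phantom_spec`, `make_phantom_volume`, `slice_and_perturb`,
`render_film`, `make_group_study`) produces synthetic studies with known
ground truth, and the whole validation is property-based against that
truth.

## The phantom: what it emulates, and what it deliberately is not

A phantom is a brain-shaped activity volume: an egg-shaped outer shell
(dorsal/ventral asymmetric) that tapers along z, containing nested
ellipsoidal structures at distinct baseline activities (defaults: shell
60, "hippocampus" 120, "thalamus" 90 nCi/g). Structure boundaries are
blended with a mask-aware Gaussian so in-brain values interpolate between
the baselines; i.i.d. Gaussian noise (default sd 2 nCi/g) is added inside
the brain.

Three design choices matter and were made for identifiability:

* **Bilateral mirror symmetry.** Internal structures come in pairs
  mirrored about the midline, as real coronal anatomy does. Beyond
  realism this has a precise function: for midline-symmetric content the
  pair-registration cost is an *even* function of the rotation angle, so
  the slow section-to-section change of anatomy cannot masquerade as a
  rotation. One-sided structures leave a per-pair rotation bias
  (the shrink field of a changing off-center cross-section has a curl that
  rigid NCC reads as rotation) which a sequential chain accumulates;
  mirrored pairs cancel it exactly, leaving at most a small translation
  along the symmetry axis.
* **Noise level.** Film grain digitized at 10 µm pixels amounts to roughly
  1–2 gray levels of noise; with the default standards (≈0.6 nCi/g per
  gray step) that is ≈2 nCi/g, the default. Contrast between structures
  (30–60 nCi/g) dwarfs it, as on real films.
* **Two z-profiles.** `z_profile = "truncated"` (default) leaves tissue in
  the first and last section, as when a bregma range of a larger brain is
  sectioned — right for testing the section pipeline. `z_profile =
  "closed"` closes the outline inside the grid so the whole brain is in
  the field of view — required when testing recovery of synthetic 3D
  transforms, because content cut at the volume boundary otherwise
  confounds the estimate, most visibly as spurious z-scale.

Group studies add per-subject variability: a ±2% geometry jitter, a
global intensity factor N(1, 0.03), and a smooth random B-spline warp
(control-point sd 5 µm) standing in for local anatomical differences that
an affine cannot express. Group B receives a regional activation:
activity × (1 + effect size) inside a ground-truth mask, applied before
the warp so the effect travels with the anatomy. Film rendering inverts
the standards curve, quantizes to 8 bits (round-half-up, clamped as film
saturates), and plants dust speckles and shifted partial tissue copies as
artifacts.

What the phantom does *not* model: film exposure dynamics and response
curves, cryostat cutting physics (tears, folds, compression),
photorealistic texture, and anatomically detailed structures. Passing
tests therefore demonstrate the correctness and accuracy of the
*algorithms* under a controlled forward model, not performance on every
pathology of real film material.

## Numerical choices

**Registration metric.** All registrations maximize NCC, evaluated over
the *fixed image's* mask intersected with nothing but the moving field of
view, with out-of-field samples reading as background 0. Two textbook
alternatives were rejected for measured reasons: intersecting with the
nearest-neighbour-resampled moving mask makes the cost discontinuous in
the transform (mask pixels flip in and out), and letting the metric
region vary with the overlap biases the optimum toward transforms that
exclude hard-to-match voxels (overlap-selection bias, most visible in the
recovered z-scale).
The fixed-region, zeros-outside form is continuous and region-constant.

**Metric smoothing.** The metric inputs (never the outputs) are smoothed:
sections with σ = 1.2 px and a 4-px dilated fixed mask so both sides of
the tissue outline contribute; volumes with FWHM = 3 × voxel. This
suppresses noise-driven displacement of the optimum and the interpolation
ripple sharp edges cause. For volume registration the fixed image gets an
extra √(1/3)-voxel blur matching the trilinear interpolation blur a
moving volume accumulates over its two interpolation passes (its own
generation or reconstruction, and the metric's resampling); without this
the recovered scale is biased at the percent level.

**Optimizers.** Rigid 2D: a deterministic coarse search (±5 coarse-pixel
translations × rotation offsets {−8, −4, 0, 4, 8}°) followed by
Nelder–Mead, then full-resolution Nelder–Mead refinement; if nothing beats
the initialization, the initialization is returned and flagged. Affine:
Nelder–Mead per pyramid level (×4, ×2, ×1) with scaled parameters and a
fresh-simplex restart at the finest level (12-dimensional simplexes
routinely stall once). B-spline: L-BFGS-B on the control-point
displacements with the analytic NCC gradient — the exact spatial gradient
of the trilinear interpolant, chain-ruled through the cubic spline basis;
grid schedule from 1/4 to 1/8 of the extent (floored at the 2-voxel
legality limit for thin stacks). Everything is deterministic; the only
RNG in the package is the phantom generator and the optional permutation
test, both seeded.

**Sequential-chain behaviour.** The center-out chain anchors the global
frame at the lower central section; the global pose of a reconstruction
is arbitrary and no z-straightening is attempted (no 3D reference exists
at this stage). An already-aligned stack is a fixed point only up to the
per-pair metric noise floor (≤0.5 px, ≤0.5°): the metric optimum under
noise sits slightly off identity; a snap-to-identity deadband large
enough to hide this would also swallow genuine sub-pixel corrections,
whose metric improvements are of the same magnitude, and so degrade
chain accuracy.

**Statistics.** Pooled-variance t (Welch optional), df = n_A + n_B − 2,
positive t meaning group B above group A; zero-variance voxels are
excluded and counted rather than assigned p = 1, so they do not inflate
the FDR denominator. Global proportional scaling is on by default: with
groups of 8, a chance imbalance in global uptake otherwise produces
brain-wide pseudo-activations — the standard failure mode that global
normalization exists to prevent in voxel-wise metabolic mapping. FDR is
Benjamini–Hochberg; FWE is Bonferroni by default with an exact/randomized
permutation max-T alternative (exhaustive enumeration when the number of
distinct relabelings is small). Cluster filtering uses 26-connectivity.

When the false-discovery rate is *measured* against the phantom's
ground-truth region, discoveries in a guard band around the region (the
truth mask dilated by the smoothing support, 4×4×2 voxels) are not
counted as false: the per-subject anatomy warp and the 3-voxel smoothing
spread genuine signal a few voxels past the nominal boundary.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| in-plane pixel size | 10 × 10 | µm | film digitization resolution |
| section thickness `dz` | 20 | µm | cryostat sectioning |
| opening radius | 50 (30 in pipeline configs for small phantoms) | µm | disk element; separates dust/overlaps without eating tissue |
| calibration method | natural spline | — | piecewise-linear fallback available |
| out-of-range gray | clamp | — | mirrors film saturation; `error` for QC |
| registration downsample | 4 | — | coarse stage reduction |
| template smoothing | 3 × voxel | FWHM | regularizes the reference |
| statistical smoothing | 3 × voxel | FWHM | SNR and residual anatomy mismatch |
| FDR level `q` | 0.05 | — | user choice |
| FWE level `alpha`, method | 0.05, Bonferroni | — | permutation max-T optional |
| cluster size | user | voxels | applied after voxel thresholding |

## Problem sizes used in validation

The test-suite and the acceptance script validate at desk scale: phantoms
of 64 × 64 × 40 voxels (10 × 10 × 20 µm), perturbations ±100 µm / ±5°,
groups of 8 vs 8, 10–20 seeded replicates per property, and end-to-end
pipeline runs on 40 × 40 × 10 studies of 2 + 2 subjects. These sizes keep
a full validation run in the tens of minutes while leaving every
algorithmic path identical to a full-size study (150 sections of
~400 × 500 px); only array sizes change.

## Known limitations

* Sequential stacking cannot recover smooth low-frequency trends of the
  true section positions (the "banana" ambiguity): with no 3D reference,
  a slowly bending spine is indistinguishable from anatomy.
* Reconstructed volumes are cut at the first/last section; the
  normalization metric treats beyond-boundary samples as background,
  which slightly penalizes transforms that map tissue across the cut.
* The t-test's per-voxel calibration is only approximate where the
  between-subject distribution is non-Gaussian (structure boundaries
  under geometry jitter); measured null suprathreshold fractions are
  mildly conservative.
* BH-FDR under the strong positive dependence induced by smoothing has a
  heavy-tailed false-discovery proportion: single replicates can exceed
  the nominal level even though the mean is controlled.
* The standards strip is consumed as a (gray, activity) table; reading
  gray levels off a standards-strip image is out of scope.
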