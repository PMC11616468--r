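---
title: "Quantifying respiratory motion with vector volume histograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying respiratory motion with vector volume histograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vvhmotion)
```

## The problem

Tumors in the thorax and upper abdomen move with breathing. Whether that
motion warrants management (gating, breath-hold, tracking) is usually
decided from respiration-correlated CT, and the standard point measures —
the displacement of a contour's centroid, or of a few edge points, between
end-inspiration and end-exhalation — collapse a deforming volume into a
single number. The vector volume histogram (VVH) keeps the volumetric
information: every voxel of the contoured structure contributes its own
displacement length, and the distribution of those lengths is summarised
the way a dose-volume histogram summarises dose.

## Data model and conventions

All containers share one grid convention: axes in (LR, AP, CC) order,
0-based voxel indices, a voxel's world position is its centre, and
`world = origin + index * spacing` in mm. On disk everything is NIfTI-1
in canonical RAS orientation; scalar volumes in another orientation are
reoriented on read, while displacement fields (4D, three mm components on
the last axis) are required to be canonical already, because reorienting a
vector image also permutes and re-signs its components and a silent
reorientation would be easy to get wrong.

The displacement field is *pull-back* (fixed-to-moving): at each fixed
voxel centre it points to where the same anatomy sits in the moving image.
That is the choice that makes "motion of the structure delineated on the
fixed image" well defined; nothing in the analysis depends on the sign
convention because per-axis lengths are absolute values. Components are
stored signed and made absolute only at analysis time.

A voxel belongs to the structure iff its centre lies inside the mask, and
every member voxel carries the same volume weight (the grid is uniform).
Partial-volume weighting at the contour surface is deliberately not
attempted: at the 1–2.5 mm spacings involved it changes the indices by far
less than registration error does.

## The registration stage

The deformation is a cubic B-spline free-form deformation: a uniform
lattice of control-point coefficients (mm), blended at each voxel by
tensor products of the cubic B-spline basis over the 4×4×4 neighbouring
control points. The lattice extends past the image domain so every voxel
has full support. Registration minimises the mean squared intensity
difference (SSD) between the fixed image and the moving image sampled
(trilinear, nearest-edge clamped) at the displaced positions, plus a small
bending-energy penalty — the mean squared second difference of the
coefficients along each lattice axis scaled by the control spacing — that
discourages oscillatory solutions. SSD assumes both images share one
intensity scale, which holds for two phases of one CT study; to make the
metric and step sizes scale-free the two images are jointly rescaled to
[0, 1] before optimisation.

Optimisation is deterministic: coefficients start at zero and are updated
by gradient descent (the SSD gradient is analytic through the B-spline
basis and the trilinear interpolant) with a backtracking-and-expanding
line search along the ∞-norm-normalised descent direction, so one step
moves no coefficient by more than the current step length in mm. There is
no stochastic sampling anywhere, hence no seed: two runs are
bit-identical.

Three multi-resolution levels are used. Images are smoothed with a
separable Gaussian (σ = downsampling factor, in voxels) and decimated by
4/2/1; the control spacing is 64/32/16 mm across the levels, and between
levels the lattice is refined by exact dyadic B-spline subdivision, so the
represented field is unchanged (to floating point) before the next level
starts. The heavy coarse-level smoothing is what gives the method its
capture range: a 2 cm target shifted by a full 2 cm barely overlaps
itself, and only after blurring does the metric landscape slope toward
the right optimum.

Defaults that matter:

| parameter | default | why |
|---|---|---|
| `control_spacing` | 16 mm (finest level) | fine enough to follow a 2 cm target, coarse enough to stay smooth and fast |
| `levels` | 3 (×4/×2/×1) | capture range for shifts up to ~20 mm |
| `max_iterations` | 50 per level | the line search makes iterations cheap to saturate |
| `regularization_weight` | 1e-3 | mild smoothing; SSD on [0,1] intensities dominates |
| `convergence_tol` | 1e-6 relative | stop early when a level stalls |

The final field is guaranteed never to score worse than the zero field at
full resolution (the zero field is returned in the degenerate case, e.g.
structureless images).

## From field to indices

For direction d ∈ {LR, AP, CC}, each member voxel contributes |u_d|; for
the 3D vector it contributes √(u_LR² + u_AP² + u_CC²). The VVH curve
evaluates, at bin edges 0, w, 2w, … past the maximum length, the
percentage of structure volume with length ≥ the edge; it starts at 100%
and is 0 beyond the maximum. The default bin width is 0.1 mm — an order
of magnitude below voxel spacing, so binning never visibly quantises a
curve. A length exactly on an edge counts as "at least" that edge, with a
1 nm tolerance absorbing the binary representation of decimal widths.

The indices are *not* read off the binned curve. L_min and L_max are the
extreme lengths; L_x% is computed from the raw per-voxel lengths as the
(100−x)-th percentile with linear interpolation between order statistics
(for n lengths, rank h = (n−1)p + 1 interpolated), avoiding bin-width bias
and making the value independent of any curve parameter. The footnote
semantics "x% of the organ moved by at least this length" force the
descending-cumulative convention and the ordering
L_min ≤ L_95% ≤ L_50% ≤ L_5% ≤ L_max, which is asserted property-style in
the tests. The motion-management flag compares one index (default L_50%
of the 3D vector) *strictly* against the threshold (default 5 mm): a
motion of exactly 5 mm is not flagged.

Degenerate inputs are hard errors, never silently repaired: empty masks,
non-finite intensities or displacements, mismatched grids, non-positive
bin widths, and displacement files with a component count other than 3
all raise classed validation/I-O conditions (which the CLI maps to exit
codes 2 and 1).

## The digital phantom

The generator emulates a dynamic thorax QA phantom: an elliptical
body-equivalent cylinder (0 HU, 55×45 mm semi-axes) in air (−1000 HU),
containing a 30 mm radius lung-equivalent rod (−700 HU) with a 2 cm
water-equivalent sphere (0 HU). The materials are described by their
tissue equivalence, so the HU values are chosen as realistic CT numbers
for those materials rather than measured ones. The default grid is 1.25 mm
isotropic over ≈120×120×150 mm — matching the slice thickness of the
validation scans and making 5/10/15/20 mm cranio-caudal shifts exact
multiples of the voxel size — with a 2.5 mm `coarse` preset (the patient
scan's slice thickness) for fast runs. The moving volume re-voxelises the
shifted sphere rather than shifting voxels, so sub-voxel shifts are
representable; noise is off by default, with seeded Gaussian noise
available. A cosine breathing series maps phase p of P to a cranio-caudal
offset amplitude·(1 − cos 2πp/P)/2, so 0% is end-inspiration and 50%
end-exhalation.

What the phantom does *not* emulate: real lung texture (the rod is
uniform, so the registration is driven purely by the sphere and rod
boundaries), hysteresis over the breathing cycle, target deformation (the
sphere translates rigidly), rotation of the physical rod, and scanner
artefacts. Passing the phantom recovery test therefore demonstrates
correct geometry, capture range and index arithmetic — not clinical
registration accuracy on textured anatomy, where intensity-based DIR is
known to depend strongly on local image content.

## Validation problem sizes

The test suite exercises the full pipeline at the phantom's native
1.25 mm spacing (96×96×120 voxels, four registrations at shifts
5/10/15/20 mm) for the recovery bound — mean |L_x% − shift| over
x ∈ {95, 50, 5} below 1 mm — and uses the 2.5 mm preset (48×48×60) for
unit-level registration checks. Oracle tests pin the fast paths to naive
reference implementations: lattice evaluation against a triple-loop
polynomial-basis summation on ≤16³ grids (≤1e−9 mm), the percentile
indices against an independent sort-and-interpolate rule (≤1e−9 mm), and
the SSD sampler against a brute-force trilinear resampler.

## Known limitations

* No folding prevention: the transform's Jacobian is not constrained;
  bending energy only discourages folds. For QA-scale rigid shifts this
  never bites, but grossly non-diffeomorphic solutions are not excluded.
* SSD only; registering across modalities or after contrast change would
  require a mutual-information metric, which is out of scope.
* L_min and L_max inherit the registration grid's worst single voxel and
  should be read with care; the percentile indices are the stable ones.
* The VVH discards spatial location: it reports how much volume moves how
  far, not where. Visual inspection of the registration remains essential.
* Masks are analysed on the fixed-image grid; a contour propagated to the
  moving phase is not required and not used.
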