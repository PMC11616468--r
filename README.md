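# vvhmotion

Volumetric quantification of respiratory-induced organ and tumor motion
from deformable image registration (DIR), for radiotherapy treatment
planning and QA.

Point measures of tumor motion — the displacement of a contour's centroid
or of a few edge points between breathing phases — ignore that a structure
deforms: different parts of a tumor move by different amounts. `vvhmotion`
implements the **vector volume histogram (VVH)**, the motion analogue of
the dose-volume histogram. A dense deformation vector field (DVF) between
two CT volumes is restricted to a contoured structure, each member voxel
contributes one displacement length, and the distribution is summarised as
a descending cumulative curve and a handful of indices. It is aimed at
medical physicists evaluating whether a patient needs respiratory motion
management (gating, breath-hold, tracking), which is commonly recommended
when tumor motion exceeds 5 mm.

## Method

Given fixed (e.g. end-inspiration) and moving (e.g. end-exhalation)
volumes, an intensity-based cubic B-spline free-form-deformation
registration produces per-voxel displacements u = (u_LR, u_AP, u_CC) in mm
on the left-right / anterior-posterior / cranio-caudal axes. Over the
voxels of a structure mask, the per-voxel length is |u_axis| for a single
direction or the 3D magnitude

    ||u|| = sqrt(u_LR^2 + u_AP^2 + u_CC^2).

The VVH curve gives, for each length L, the percentage of the structure
volume that moved **at least** L. From the raw lengths the package
computes the motion indices

| index | meaning |
|---|---|
| L_min, L_max | extreme per-voxel displacement lengths |
| L_95% | length that 95% of the volume moved at least (a "nearly everywhere" floor) |
| L_50% | median motion of the volume |
| L_5%  | length reached by the most mobile 5% of the volume |

so L_min ≤ L_95% ≤ L_50% ≤ L_5% ≤ L_max always. A centroid-displacement
baseline (the classical point measure) and a >5 mm motion-management flag
are included, as is a digital moving-thorax phantom — a 2 cm
water-equivalent sphere inside a lung-equivalent rod with programmable
shifts and analytic ground truth — used for all validation.

## Worked example

```r
library(vvhmotion)

# digital phantom with a 10 mm cranio-caudal target shift, 1.25 mm voxels
ph <- generate_phantom(phantom_spec(shift = c(0, 0, 10)))

field <- register(ph$fixed, ph$moving)          # B-spline DIR, ~2 min
idx <- compute_indices(extract_lengths(field, ph$target_mask, "VEC3D"))
print(idx)
#> L_min 9.96  L_95% 10.00  L_50% 10.11  L_5% 10.27  L_max 10.30 (mm)

flag_motion_management(idx)                     # L_50% > 5 mm ?
#> [1] TRUE

# centroid baseline between the two target delineations
mv <- generate_phantom(phantom_spec(target_center = c(0, 0, 10)))
print(centroid_displacement(ph$target_mask, mv$target_mask))
#> centroid displacement: LR 0.000, AP 0.000, CC 10.000, 3D 10.000 mm
```

All five indices sit within ~0.3 mm of the programmed 10 mm shift: the
registration recovered the motion of the whole target volume, and the
centroid of the integer-voxel (8 × 1.25 mm) translation is exact. The same
pipeline runs from the shell:

```sh
Rscript inst/cli/vvh.R report --out-dir out --shift-cc 10
Rscript inst/cli/vvh.R analyze --field dvf.nii.gz --mask gtv.nii.gz --out-dir out
```

(`phantom`, `register`, `analyze`, `centroid`, `report` subcommands; exit
codes 0 success / 1 I/O error / 2 validation error.)

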