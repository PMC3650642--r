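# habseg

Landmark-guided segmentation and volumetry of the human habenula on
high-resolution T1-weighted MRI.

The habenula is a pair of epithalamic nuclei of ~30 mm^3 per side — smaller
than a standard fMRI voxel — lying between the third ventricle, the
mediodorsal (MD) thalamus and the posterior/habenular commissure (PC/HC).
`habseg` is for researchers who need subject-specific habenula ROIs and the
statistics around them:

* **AC–PC reorientation** — a proper rigid motion placing the anterior
  commissure at the origin, the PC on the −y axis and the midsagittal plane
  at x = 0, computed from three manually placed landmarks. Header-only by
  default (aligned but never resampled); explicit opt-in resampling for
  slice-wise tracing.
* **Geometric delineation** — in posterior coronal slices (PC/HC present)
  the lateral habenula boundary is built from per-slice landmarks A, B, C:
  the lateral edge through B and C, the ventral edge horizontal from A, and
  their intersection as the ventrolateral apex; the triangle [A, B, apex]
  is filled on the voxel grid. Anterior slices use seeded, contrast-bounded
  2D region growing with an intensity threshold
  τ = (MD mean + seed-region mean)/2.
* **Volumetry** — exact voxel-count volume, unweighted centre of mass in
  world mm, coronal slice span with the 3–5-slice plausibility check at
  0.77 mm spacing.
* **Inter-rater reliability** — ICC(2,1): two-way random-effects,
  absolute-agreement, single-measures intraclass correlation,
  ICC = (MSR − MSE) / (MSR + (k−1)MSE + (k/n)(MSC − MSE)),
  with F-based 95% confidence intervals and qualitative banding.
* **Smoothing contamination** — the fraction of post-smoothing signal in a
  habenular ROI that originated in surrounding structures, as a function of
  Gaussian kernel FWHM.
* **Synthetic phantom** — an analytic epithalamic neighbourhood with
  ground-truth masks, landmarks and simulated raters, so the entire
  pipeline is testable without real scans.

## Worked example

```r
library(habseg)

# A 64^3 phantom at 0.77 mm with ~30 mm^3 habenulae and ground truth
ph <- generate_phantom(seed = 1, noise_sigma = 0)
ph
#> <hab_phantom> 64x64x64 voxels at 0.77 mm; true volumes L 29.7 / R 29.7 mm^3

# Reorient: the phantom's AC/PC/midsagittal landmarks are already aligned
tr <- compute_acpc_transform(ph$acpc)

# Trace the right habenula from the ground-truth landmarks:
# geometric triangles in PC/HC-containing slices, region growing anteriorly
roi <- delineate_habenula(ph$image, ph$slice_landmarks$right,
                          anterior = ph$anterior$right,
                          posterior_y = ph$params$posterior_y,
                          anterior_y = ph$params$anterior_y)
measure_mask(roi)
#>            label n_voxels volume_mm3    com_x     com_y    com_z slice_span_y
#> 1 right_habenula       65   29.67464 3.334692 -24.54523 2.866769            3
```

65 voxels at 0.77 mm isotropic give 29.67 mm^3, recovering the ground
truth exactly on the noise-free phantom; the centre of mass sits ~3.3 mm
right of the midline, ~24.5 mm posterior to the AC and ~2.9 mm dorsal to
the AC–PC plane, and the ROI spans 3 coronal slices — all within the
plausible adult ranges for this structure.

```r
# Two simulated raters over repeat tracings -> absolute-agreement ICC
r1 <- simulate_rater(ph$true_masks$right, boundary_sd = 0.4, seed = 11)
r2 <- simulate_rater(ph$true_masks$right, boundary_sd = 0.4, seed = 12)

# How much ROI signal would smoothing import from neighbours?
contamination_curve(ph$labels, "habenula_right", c(0, 2, 3, 5, 8, 12))
#>   fwhm  fraction
#> 1    0 0.0000000
#> 2    2 0.5788308
#> 3    3 0.7379384
#> 4    5 0.8910048
#> 5    8 0.9623764
#> 6   12 0.9852177
```

At the 5–10 mm FWHM kernels common in group fMRI analyses, ~90% or more of
the smoothed "signal" inside the habenula ROI originates in neighbouring
structures — the quantitative case for high-resolution acquisition and
minimal smoothing when studying this nucleus.

A thin command-line wrapper over the same functions is installed at
`inst/cli/habseg` (subcommands `reorient`, `trace`, `measure`, `icc`,
`contamination`, `phantom`).

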