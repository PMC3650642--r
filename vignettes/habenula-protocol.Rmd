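---
title: "Delineating and measuring the habenula on high-resolution T1-weighted MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and measuring the habenula on high-resolution T1-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habseg)
```

## The problem

The habenula is a pair of epithalamic nuclei of roughly 30 mm^3 per side,
sitting immediately dorsal to the posterior commissure (PC), medial to the
mediodorsal (MD) thalamus and protruding into the cerebrospinal fluid (CSF)
of the third ventricle. At that size it is smaller than a single voxel of a
standard fMRI acquisition, and the 5–10 mm FWHM smoothing kernels of
conventional group analyses are larger than the structure itself. Reliable
study of the habenula therefore needs (a) a reproducible way to trace it on
high-resolution (~0.77 mm isotropic) T1-weighted images, (b) volumetry and
inter-rater agreement statistics for the resulting ROIs, and (c) a
quantitative handle on how badly smoothing mixes signal from neighbouring
structures into a habenular ROI. This package implements all three, plus a
synthetic phantom of the epithalamic neighbourhood so the entire pipeline
can be validated without access to real scans.

## Coordinate conventions

All geometry is done in world millimetres under RAS+ (+x right, +y
anterior, +z superior). Voxel indices are 0-based and the 4x4 affine maps
voxel *centres* to world coordinates — the dominant NIfTI convention.
`read_volume()` canonicalizes any stored axis order to RAS+ without
changing the world coordinate of any voxel centre; masks are written with
the source image's affine verbatim, never resampled on write.

## AC–PC reorientation

Tracing is defined in the commissural frame: the origin at the midpoint of
the anterior commissure (AC), the PC at the same x and z as the AC (so the
AC–PC line runs along -y), and the brain symmetric about the sagittal plane
x = 0 containing that line. `compute_acpc_transform()` builds the unique
proper rigid motion with these properties from three user-supplied points
(AC, PC, and any midsagittal-plane point well away from the AC–PC line; the
roll about the AC–PC axis is fixed by that third point, mapped into the +z
half-plane, rather than by automated symmetry optimisation — the protocol
is deliberately landmark-driven and deterministic). Landmark sanity is
enforced: AC–PC distances outside 15–40 mm warn, angular separation of the
midsagittal point below 5 degrees from the AC–PC line is a hard error.

Two application modes exist. The default, `apply_transform_header()`,
composes the transform into the affine and never touches the data: the
image is aligned but not spatially transformed, preserving the native
resolution (every re-slicing step degrades effective resolution slightly).
`resample_to_acpc_grid()` is the explicit opt-in for users who need grid
axes aligned with the commissural frame for slice-wise tracing; it
interpolates exactly once, trilinearly for intensities and
nearest-neighbour for masks so they stay binary. No symmetry tolerance is
imposed after reorientation; `midsagittal_residual()` reports the residual
|x| of the midsagittal landmark as a QC number instead.

## Delineation

The habenula appears *brighter* than the adjacent MD grey matter on
T1-weighted images because of its dense white-matter plexuses; its medial
boundary is the dark CSF of the third ventricle. The lateral boundary in
posterior slices — those in which the PC (or habenular commissure, HC) is
visible — cannot be followed by contrast alone, so it is constructed
geometrically from three per-slice landmarks:

* **A** — intersection of the medial habenula boundary with the PC/HC;
* **B** — dorsal point of the medial boundary where it meets the MD;
* **C** — lateral aspect of the mesopontine junction by the tentorial
  incisure (treated purely as a user-supplied coordinate; its role is only
  to direct the lateral edge).

The lateral edge is the straight line through B and C; the ventral edge
runs horizontally and laterally from A; the ventrolateral apex is their
intersection (`apex_from_landmarks()`); the medial edge connects A to B.
The source description labels two different segments "line z"; the only
consistent reading, and the one implemented, takes the B–C lateral edge,
the A–B medial edge and the horizontal ventral edge as the three distinct
lines whose intersection defines the apex. The filled triangle [A, B, apex]
is the slice ROI (`posterior_slice_polygon()`, `rasterize_polygon()`).
Rasterization is inclusive: a voxel centre lying exactly on the polygon
boundary counts as inside, which operationalises the rule that ambiguous
dark-grey voxels at the medial boundary are included. An optional second
mechanism, `include_ambiguous_medial()`, additionally admits a one-voxel
medial rim restricted to intensities strictly between the CSF reference and
the ROI mean; both behaviours are explicit in the API because the
underlying rule is qualitative.

In the most anterior slice(s), where the PC/HC is absent, the stria
medullaris and fasciculus retroflexus provide enough contrast to follow the
boundary directly: `anterior_slice_roi()` grows a 4-connected 2D region
from a user seed, accepting voxels at least as bright as the midpoint
between the MD reference mean and the seed-neighbourhood mean, clipped to a
4 mm half-width box. Reaching the clip box on two or more sides is
diagnosed as leakage (insufficient contrast) and raises an error rather
than returning a silently wrong ROI.

`assemble_roi()` unions contiguous slices and validates the
anterior–posterior span: at 0.77 mm spacing the habenula occupies three to
five coronal slices; the bound is rescaled proportionally for other
spacings and violations warn. The anterior and posterior boundary slices
are the user's call on real data (the tool takes explicit bounds and
validates them); on phantoms, ground truth supplies them. Mapping a y
coordinate to a slice uses the nearest slice, with exact midpoints rounding
toward posterior — deterministic, and biased toward the PC-containing
slices where the geometric rule is defined. Medial and lateral habenular
nuclei are never distinguished; the ROI is a single combined habenula.

## Volumetry

`mask_volume()` is foreground voxel count times the affine's voxel volume;
`mask_center_of_mass()` is the unweighted mean of foreground voxel-centre
world coordinates (the ROIs are binary, so intensity weighting is out of
scope). Volume is exactly invariant under header-only reorientation and
centroids transform exactly by the rigid motion; both properties are
asserted in the tests.

## Inter-rater reliability

`icc_2_1()` implements the two-way random-effects, absolute-agreement,
single-measures intraclass correlation ("Model 2"), the standard statistic
for agreement between two raters each tracing every subject:

ICC(2,1) = (MSR − MSE) / (MSR + (k−1) MSE + (k/n)(MSC − MSE))

where MSR, MSC and MSE are the subject, rater and residual mean squares of
the two-way ANOVA. Absolute agreement means systematic offsets between
raters count against reliability. The 95% interval is the conventional
F-based interval for this model (McGraw & Wong 1996); the originating
protocol names the model but not its CI formula, so our intervals are
documented as this choice and not expected to reproduce any particular
published interval digit-for-digit. Banding follows the usual qualitative
ranges (0.81–1.00 "almost perfect", 0.61–0.80 "substantial", 0.41–0.60
"moderate", 0.21–0.40 "fair", 0.00–0.20 "slight"); since the printed
ranges abut at two decimals, values in the gaps belong to the upper band
(0.205 is "fair"), and negative estimates are reported as computed and
banded "slight".

## Smoothing contamination

`contamination_fraction()` quantifies the Discussion-level concern
directly: label every non-target tissue voxel 1 and the target (and
unlabelled background) 0, smooth with the Gaussian under test, and average
over the target mask the per-voxel share of smoothed signal that originated
outside the target — smoothed(outside tissue) / smoothed(all tissue). The
fraction is defined purely from labelled tissue, so empty background
neither contributes nor dilutes; it is exactly 0 at FWHM 0 and tends to the
complement's local tissue share (→ 1 for a small target) as the kernel
grows. Because it puts unit signal everywhere outside the ROI it
upper-bounds mixing independent of true effect sizes.

Smoothing is separable convolution specified in world mm (per-axis sigma =
FWHM/√(8 ln 2) divided by the voxel size, so anisotropic grids are
handled), with the kernel truncated at 4 sigma and renormalized to unit sum
where it overhangs the grid edge (normalized convolution over zero
padding). This boundary rule keeps constant images exactly invariant and
makes the separable implementation agree with a dense 3D
truncated-and-renormalized convolution to machine precision, because the
truncated kernel's sum over an axis-aligned box factorises per axis — which
is exactly what the brute-force oracle in the test suite recomputes.

## The phantom

`generate_phantom()` builds the epithalamic neighbourhood analytically in
the AC–PC frame: a bright habenula pair (default target 30 mm^3 per side,
A–P extent 2.5 mm) protruding into a dark third-ventricle CSF column of
1 mm half-width, MD thalamus laterally, a PC/HC white-matter band ventrally
(containing the PC point at (0, −25, 0); the AC sits at the origin 25 mm
anterior, so reorientation can be exercised end-to-end), a pineal blob
posteriorly and stria medullaris bands anteriorly. Cross-sections are
triangular in posterior slices and rounded-rectangular ("oblong") in
anterior slices, lofted along y — the qualitative posterior-pyramidal to
anterior-oblong progression of the real structure. Default intensities are
CSF 0.3, MD 1.0, habenula 1.3, white matter 1.6 (arbitrary units; the
enforced ordering CSF < MD < habenula is the contrast premise of the
protocol), with additive Gaussian noise of SD 0.02 by default — the
originating protocol says nothing about noise, and at structural-image SNR
an additive Gaussian model is adequate for contrast-driven testing; a
contrast that survives this noise trivially survives none.

The in-plane cross-section scale is calibrated by bisection so the
*voxelised* ground-truth volume matches the requested target as closely as
the grid allows (within about one voxel volume, 0.457 mm^3 at 0.77 mm); the
grid's x axis is placed symmetric about the midline so left and right sides
voxelise identically. The generator returns everything downstream modules
need: the image, a label map, ground-truth masks and volumes, the AC/PC/
midsagittal landmarks, per-slice A/B/C landmarks for every posterior slice
(with C placed on the B–apex line beyond the apex, so the geometric
construction reproduces the generating triangle), and seed/reference
intensities for the anterior slices.

What the phantom deliberately does not emulate: MR physics (bias fields,
sequence-dependent contrast, Rician noise floors), partial-volume
intensities at structure borders, anatomical variability of the boundary
shapes, and rater perception. Passing the pipeline tests on phantoms
therefore demonstrates geometric and numerical correctness of the
implementation — not that human raters will achieve the same agreement on
real scans.

`simulate_rater()` models a human tracer as a level-set perturbation: the
signed Euclidean distance to the truth boundary is shifted by a systematic
bias (dilation/erosion) plus a smooth random field (correlation length
~1.5 mm) scaled to a given boundary SD, slice by slice, keeping the
connected component overlapping the truth. `slice_span_simulation()`
reproduces the slab-counting arithmetic behind the expected 3–5 coronal
slice span of a 2–3 mm structure at 0.77 mm slicing.

## Numerical choices and problem sizes

* Rigid rotations are validated orthonormal with det +1 to 1e-9; transform
  recovery on landmarks is exact to well below 1e-6 mm.
* Point-in-polygon uses half-plane sign tests with a 1e-9 mm inclusive
  tolerance; the test suite checks exact voxel-set equality against an
  exhaustive brute-force sweep on randomly generated triangles.
* Gaussian kernels are truncated at 4 sigma; both the implementation and
  the dense oracle use the same truncation, so their agreement tolerance
  (1e-6) reflects arithmetic only.
* The default phantom grid is 64^3 at 0.77 mm (~49 mm field of view) —
  large enough to contain the AC, PC and all labelled structures while
  keeping every test and the acceptance script fast; resolution-refinement
  tests use 0.3–0.4 mm grids sized to the same field of view.
* Monte-Carlo ICC recovery uses n = 500 subjects per table, averaged over
  replicate simulations because a single two-rater table's ICC differs from
  the closed form by a random amount comparable to the 0.02 tolerance (the
  realized rater-offset variance has one degree of freedom).

## Known limitations

Automated AC/PC detection, atlas/template registration and nonlinear
normalisation are out of scope; the tool is deliberately landmark-driven.
Point C has no operational definition beyond the user's placement. The
ventral boundary between the apex and the PC/HC is implemented as the
horizontal line from A, not as the commissure's curved dorsal surface. The
anterior/posterior boundary slices on real data remain the rater's
judgement; the package validates spans rather than choosing boundaries.
Consistency-type ICCs, average-measures ICCs and spatial-overlap agreement
(Dice/Jaccard) are not provided.
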