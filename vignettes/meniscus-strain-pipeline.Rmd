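---
title: "From volumetric MRI to regional meniscus strain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From volumetric MRI to regional meniscus strain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meniscusstrain)
```

## The problem

The menisci distribute load between femur and tibia; degeneration changes
their mechanical response and thereby the load seen by the articular
cartilage. Imaging a knee under controlled axial compression at several
fractions of body weight (BW), and registering the loaded to the unloaded
volumes, yields a dense material displacement field for the meniscus. From
that field one can compute full 3D strain tensors, decompose them into the
mechanically meaningful directions of a meniscus — axial (along the load),
circumferential (along the main collagen bundles), radial — and compare
characteristic regional strains between mildly and severely degenerated
joints.

This package implements that analysis chain as testable components:

1. `volumes_io`: raster containers (`image_volume`, `label_mask`,
   `displacement_field`), NIfTI I/O, ROI cropping.
2. `phantom`: a synthetic stand-in for the cadaver cohort — C-shaped wedge
   masks, analytic ground-truth deformation fields, MRI-like images,
   two-group cohorts of characteristic strains.
3. `registration`: rigid alignment plus a demons-style diffeomorphic
   registration with a windowed cross-correlation metric.
4. `hexmesh`: voxel-resolution hexahedral meshing and nodal sampling of the
   displacement field.
5. `meniscus_geometry`: cylindrical frame from a circle fit; division into
   ARA, AH, PI, PH, PRA and inner/outer zones.
6. `strain_field`: element strain tensors and their cylindrical components.
7. `summaries`: regional medians (the characteristic strains) and Dice
   overlap reporting.
8. `cohort_stats`: the nonparametric battery (Mann-Whitney, Friedman,
   paired Wilcoxon, Kruskal-Wallis, Shapiro-Wilk) with Holm or Bonferroni
   multiplicity control.

## Grid and sign conventions

One convention is used everywhere: voxel index `(i, j, k)` (1-based) has its
center at `origin + (i-1, j-1, k-1) * spacing` in mm; array axes are
(sagittal, coronal, axial) and the load acts along z. Mesh nodes live on the
corner lattice, offset half a voxel from the centers, so each element is
exactly the voxel box and its centroid is exactly the voxel center — the
point where the displacement sample natively lives. NIfTI headers with
rotated or sheared grids are rejected rather than reinterpreted: the
geometry downstream assumes axis-aligned voxels.

Compressive normal strain is negative; tension positive. Reported regional
values are in percent. The displacement convention is material: `x + u(x)`
maps an unloaded (reference) position to its loaded position, so strains
derived from `u` are strains of the tissue relative to the unloaded state.

## Registration

Loaded volumes are first rigidly aligned (6 parameters, Nelder-Mead over a
2-level pyramid, correlation metric restricted to the anatomy mask — either
the masked fixed intensities or the smoothed mask itself; both are exposed
because an interactive workflow could have used either). The non-rigid stage
is a demons-style scheme with the classic parameter semantics:

* **metric**: windowed (local) normalized cross-correlation, window radius
  2 voxels;
* **step size** 0.25 voxel: per iteration the metric-gradient force is
  scaled so a typical strong update moves a quarter voxel, and any single
  voxel is clamped to the same bound so isolated boundary artifacts cannot
  throttle the interior;
* **regularization**: the update field is smoothed with a Gaussian of sigma
  3 voxels. This is fluid-like (`Gauss[3, 0]`) regularization: the stated
  sigma acts on the metric-gradient field, not on the accumulated field. A
  light diffusion term (`total_field_sigma`, default 0.5 voxel) additionally
  smooths the accumulated field each iteration; it suppresses voxel-scale
  noise that would otherwise be amplified by differentiation into strain,
  while leaving smooth displacement profiles essentially untouched.
* **pyramid**: four levels, factor 2, iteration caps 1000/500/250/100
  coarse-to-fine; a level ends when the relative decrease of the energy
  (1 − mean local correlation over the foreground) falls below 1e-6, when
  the trust region collapses after repeated energy increases, or at the cap.

During development the accumulated field was initially smoothed with the
full sigma-3 Gaussian as well (diffusion-like regularization). That variant
recovers displacements but systematically attenuates their gradients: on a
wedge phantom with region-wise prescribed axial strain the regional medians
came out a factor ~3 too small. With fluid regularization plus the light
diffusion term, recovered regional medians track ground truth within a
quarter of a percentage point on the bump phantom at full scale. This is the
package's own design choice; exact numerical agreement with any particular
registration package is not a goal — known-warp recovery is the correctness
criterion (median endpoint error ≤ 0.5 voxel, 95th percentile ≤ 1.5 voxels
inside the mask).

The scheme is fully deterministic: identical inputs and configuration give
bit-identical fields.

## Strain kinematics

Each foreground voxel becomes an 8-node hexahedron; nodal displacements are
trilinear interpolations of the voxel-center field (clamped-edge
extrapolation at the surface, because zero-padding would fabricate surface
strain). For a rectangular trilinear element the displacement gradient at
the centroid reduces to face-averaged corner differences; it is exact for
affine fields and superconvergent (second order) for smooth ones, which the
refinement tests verify. The default measure is infinitesimal strain,
`(G + G')/2`; Green-Lagrange `(F'F - I)/2` is available for sensitivity
checks. Observed strains are below ~10 %, where the two coincide to first
order; a 1-degree rigid rotation leaves an infinitesimal residue of order
1.5e-4 (gamma^2/2) and zero Green-Lagrange strain, as the tests assert.

Cylindrical components are quadratic forms of the tensor with the local
orthonormal basis at the element centroid. Elements whose centroid lands on
the cylinder axis (radius below tolerance) are flagged and excluded from the
in-plane components; they keep their Cartesian tensors.

## Regional division

The per-meniscus frame comes from an algebraic (Kasa) circle fit to
outer-rim points — supplied explicitly, as an interactive workflow would, or
auto-extracted as the outermost body element per angular bin. The fit is
exact on exact-circle points; for noisy rims it approximates the geometric
fit, and the tests compare it against a brute-force distance-minimizing fit.
Points are used as given: no spline resampling is applied before the fit,
which is the simplest well-defined reading of an interactively picked rim.

Two separation lines (angles from the origin) cut off the root attachments;
the remaining internal angle is divided by three into AH, PI, PH, with
element membership decided by the centroid angle. The body arc is taken in
the orientation that contains the majority of elements, which removes the
wraparound ambiguity an interactive operator never faces. Zones split each
body region at the inner two-thirds of the local meniscal width, measured
per 5-degree angular bin (the bin width is a package choice — the local
width measure was genuinely open; a 360-degree bin reproduces a global-width
variant). Attachments are never zone-split; their zone is `attachment`.

## The phantom: what it emulates, and what it does not

`phantom_geometry()` defaults describe a C-shaped wedge at the study's MR
resolution (0.4 x 0.4 x 0.6 mm voxels, 96 x 96 x 32 grid): annulus radii
8–17 mm, 250-degree body span with 15-degree attachment extensions,
peripheral height 8 mm tapering to 2 mm at the inner rim — plausible adult
meniscus dimensions. Images are a bright tissue plateau over a darker
background with seeded smooth texture (so registration has structure) plus
Rician noise, the standard model for magnitude MR images; the noise sd is
config-exposed because the study's SNR is not published.

Deformation modes (`uniform_axial`, `radial`, `rigid`, `gaussian_bump`,
`wedge_axial`, `affine`, `composite`) provide analytic ground truth;
amplitudes in tests stay at or below ~2 voxels, the scale of meniscal motion
between load steps. What the phantom does **not** emulate: partial-volume
fat/fluid interfaces, intensity inhomogeneity, susceptibility distortion,
through-plane anisotropic texture, or contact mechanics of neighboring
cartilage. Passing the phantom tests therefore demonstrates correctness of
the pipeline's mathematics and robustness to Rician noise at realistic
amplitude — not performance on arbitrary clinical data.

## The synthetic cohort

`cohort_spec()` encodes the study conditions: 12 specimens per degeneration
group, medial and lateral sides, loads 25/50/100 % BW with a 60/40
medial/lateral split entering as a scale factor on per-side strain
magnitudes. Group mean characteristic strains at 100 % BW default to the
reported pattern — axial −3.1 % (mild) vs −7.3 % (severe), circumferential
+0.35/+0.45 %, radial +0.37/+0.41 % — scaled linearly to lower loads.
Configured means are treated as per-region, specimen-level means (the
source is ambiguous about the averaging base; this is the documented
choice). Group dispersions are not published; the defaults (sd 3.0 % axial,
0.5 % circumferential/radial, constant across loads) were chosen once so
that the 12 + 12 cohort detects the axial group difference with power in
the high-80s percent — comparable to the study's reported 82 % — while the
tensile-direction contrasts stay near the nominal rejection rate,
reproducing the qualitative finding that degeneration affects compressive
but not tensile behavior. Draws are independent across specimens, regions,
directions and loads (no specimen random effect); zone rows add a small
jitter (sd 0.2 %) around the region draw so region-level aggregation
reproduces the configured dispersion.

## Statistics

All tests are two-sided wrappers around the standard R implementations:
exact enumeration p-values for the rank tests at small tie-free sample
sizes, tie-corrected normal/chi-square approximations otherwise; the test
suite cross-checks them against independent brute-force enumeration oracles.
"Linear" Bonferroni correction is read as Holm's sequentially rejective
step-down procedure (the common meaning of the phrase); plain Bonferroni is
available by configuration. Completely tied Friedman blocks return a zero
statistic with p = 1 rather than NaN. The study battery groups contrasts
into the families of the original design — group (Mann-Whitney per side,
load, region, direction), location (Friedman over AH/PI/PH and over the six
body zones, with paired-Wilcoxon post hocs only after a significant
omnibus), attachment (paired Wilcoxon ARA vs PRA), load (Kruskal-Wallis
with pairwise post hocs), and a Shapiro-Wilk normality screen. The exact
multiplicity base of the original corrections is not published, so the
correction is applied within each omnibus family — the family definitions
are visible in the report so either reading can be reproduced.

## Problem sizes and numerical choices

The test suite and the acceptance script exercise the full pipeline at a
96 x 96 x 32 phantom (~30k elements) for registration recovery, and a
48 x 48 x 16 phantom (~6k elements) for the kinematics and geometry
properties; Monte-Carlo calibrations use 200–1000 replicates. These sizes
were chosen as the smallest at which the asserted properties are stable.
Other numerical choices: trilinear interpolation everywhere (exact on
affine fields); fixed-point iteration (10 steps) for backward warping and
field inversion; replicate-edge padding for Gaussian filters; truncated
windows at grid edges for the local correlation; elements are equal-volume,
so unweighted medians equal volume-weighted ones.

## Known limitations

* The registration is a simplified single-channel scheme: no symmetric
  (bidirectional) optimization, no mutual information, no explicit
  diffeomorphism guarantee beyond the smoothing and small steps.
* Strains are kinematic only — no stresses, no constitutive model, no
  inverse material identification.
* The inner/outer zone split and the attachment separation depend on the
  quality of the cylindrical frame; a poor rim fit propagates into the
  regional labels.
* Cohort draws are independent across regions within a specimen, which is a
  simplification; a specimen-level random effect would induce the
  between-region correlation real knees presumably have.
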