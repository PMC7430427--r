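---
title: "Segmenting and measuring macular holes in three dimensions"
author: "holemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and measuring macular holes in three dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holemorph)
```

## The problem

A full-thickness macular hole (MH) is a defect of the neural retina at the
fovea, spanning from the internal limiting membrane (ILM) down to the
retinal pigment epithelium (RPE). Holes are classified principally by
size -- small (&le;250 µm), medium (250--400 µm), large (>400 µm) on the
International Vitreomacular Traction Study (IVTS) scale -- and size drives
both the choice of treatment and the expected outcome. In routine care the
size is measured by a clinician with callipers on a single horizontal
SD-OCT B-scan: the minimum linear diameter (MLD) in the mid-zone of the
hole and the base diameter (BD) at the RPE. This presumes the hole is
rotationally symmetric and centred on the chosen scan. Real holes are
oval, tilted, and have their narrowest axis roughly perpendicular to the
horizontal scan direction, so 2D callipers systematically overestimate
widths and misplace the minimum.

`holemorph` implements the alternative: segment the hole in the full 3D
OCT volume, then measure everything on the reconstructed shape -- minimum
and maximum Feret diameters of the base area (BA, the cross-section in the
RPE plane) and of the minimum area (MA, the smallest cross-section in the
central 20--90% of the hole height), their meridians, heights, total
surface area, volume, and the lateral misalignment of the hole's centre
line. A synthetic phantom generator with exact analytic ground truth makes
every stage testable without clinical data, which are not distributable.

## Volume model and coordinate conventions

A volume is a grid of intensities indexed `(x, y, z)`: X runs across a
B-scan (horizontal), Y is depth within a B-scan (increasing from the
vitreous towards the RPE), Z steps across B-scans. Physical positions are
voxel index times spacing, origin at the top-left corner of the first
B-scan. The clinical protocol this mirrors acquires 768x496-pixel B-scans,
about 49 per volume, at roughly 5.47 µm/px in X, 3.87 µm/px in Y and
29--30 µm line spacing in Z -- strongly anisotropic, which is why every
kernel, distance and curvature operator in the package works in physical
micrometres rather than voxels.

## Reference surfaces and flattening

The RPE is detected per A-scan column as the dominant bright band after
Gaussian smoothing along depth (`smooth_um`, default 8 µm); the reported
position is the band's upper edge -- the half-height crossing walking up
from the peak -- because that edge is the base plane of a full-thickness
hole. The threshold references a *footprint-global* retina level rather
than a per-column one: columns inside the hole have no retina of their
own, and a per-column reference puts their RPE edge one voxel deep, which
after flattening staggers the base plane across two voxel rows and
corrupts the base section.

The ILM is the first depth, from the vitreous side, at which the smoothed
intensity exceeds half the column's peak. Inside the hole opening this
detection collapses onto the RPE; those columns (inter-surface distance
below 75% of the median retinal thickness) are treated as missing and the
membrane is spanned across the opening by harmonic inpainting. Columns at
the opening's edge, where the hole starts just below the membrane, pass
the thickness test but are still detected too deep; because this error is
strictly one-sided, a grey-scale morphological opening of the height map
(window `opening_um`, default 250 µm half-width, which must exceed the
en-face radius of the hole opening) removes the downward bump while
leaving genuine ramps such as a tilted retina untouched.

Flattening shifts each column by a whole number of voxels so the RPE
comes to a common level, making RPE-parallel planes grid slices.
Whole-voxel shifts keep the intensities bit-faithful and exactly
invertible; if a shift would push tissue off the grid, the volume is
padded, never cropped.

## Segmentation: multiscale LGDF level set

The hole is hypo-reflective against the retina, but so is the vitreous
above it, and the two are contiguous through the hole opening -- a global
two-phase model cannot isolate the hole. The segmentation therefore
evolves a signed field $\phi$ (negative inside) under a *local Gaussian
distribution fitting* (LGDF) energy: around every voxel $x$, interior and
exterior intensities are modelled as Gaussians whose means and variances
are estimated under a Gaussian window of physical scale $\sigma$
(`sigma_um`, default $3\,dx$), and the data force moves the interface
towards the region whose local Gaussian log-likelihood of $I(x)$ is
higher, with weights $\lambda_1$ (inside) and $\lambda_2$ (outside), both
1 by default. A length penalty $\mu\,\delta(\phi)\,\kappa$ (default
$\mu = 0.2$) and the distance regularisation
$\nu(\Delta\phi - \kappa)$ (default $\nu = 0.2$) complete the flow.
Intensities are min-max normalised internally, which makes the
segmentation exactly invariant under affine intensity rescaling; local
variances are floored at `min_var` ($10^{-3}$ on the unit scale) so the
noiseless limit stays finite.

Numerics worth knowing about:

* **Energy-monotone stepping.** Each iteration takes a trial step, and
  re-evaluates the full discrete energy; a step that increases the energy
  is rejected and retried at half the step size, with modest growth after
  acceptance (initial `dt` 0.1 in units of the finest voxel pitch). The
  energy trace over accepted iterations is therefore non-increasing by
  construction, which the test suite asserts. To make that line search
  effective, the length and regularisation forces are the *exact*
  gradients of their central-difference discrete energies (they reduce to
  the familiar $\mu\,\delta\,\kappa$ and $
u(\Delta\phi-\kappa)$ forms
  in the continuum); a continuum-form force on a kinked distance field
  can ascend the discrete energy at every step size. One consequence,
  deliberately accepted: in the degenerate case of a constant-intensity
  volume the geometric flow settles into a nearby stationary profile
  rather than performing ideal curvature shrinkage -- the data term,
  which drives all real use, is untouched by this, and the degenerate
  case is tested for what it robustly shows (zero data force, monotone
  energy, level-independence).
* **Convergence** is declared when the segmented volume changes by less
  than `tol` ($10^{-4}$ relative) over a 10-iteration window, armed only
  after 30 accepted iterations -- an interface inherited from a coarser
  scale is near-stationary at first and would otherwise "converge" before
  re-equilibrating. The per-scale cap is 500 iterations.
* **Multiscale schedule** (4, 2, 1) downsamples X and Y only; Z is
  already coarse. The converged coarse interface, clipped and
  re-initialised as a signed distance, seeds the next scale.
* **Domain confinement.** The working band is the inter-surface band plus
  a margin; above the ILM the evolution domain is confined to a chimney
  over the footprint of the current interior. Physically the hole
  communicates with the vitreous only through its opening; numerically an
  unconfined interface floods the (equally dark) vitreous sideways for
  hundreds of iterations before the volume stabilises.
* **Scale hand-off.** The order-0 interior handed to the next scale stops
  one voxel above the base plane, and is clipped to the band. A bright
  slab mislabelled at a coarse scale (e.g. the RPE band itself, entering
  through mixed downsampling blocks) is locally *self-consistent* under
  the LGDF statistics -- its own window average explains it -- and would
  survive refinement; forcing the finest scale to re-find the base rows
  from the data avoids that failure mode entirely.
* Ties at $\phi = 0$ count as interior; the smoothed Heaviside/delta
  width is 1.5 voxels equivalent (`eps_h_um`).

The initial seed is the set of band voxels below the 20th intensity
percentile of the band, cleaned by one morphological opening, with $\phi$
the anisotropy-aware exact Euclidean distance to the seed boundary.

## Curvature-based surface cut

After evolution the region still protrudes through the opening into the
vitreous. The cut identifies the high-curvature rim ring -- boundary
voxels within two voxels of the ILM whose mean curvature magnitude (on
the smoothed region surface) exceeds the 90th percentile of boundary
curvature -- and spans a cap surface across the rim by harmonic
inpainting of the per-column rim heights. Columns are classified as
*opening* columns when the region is contiguous across the ILM there; the
cap applies only to those (taking the shallower of rim cap and ILM, since
rim voxels sit on the mask shoulder about half a voxel deep), while any
supra-ILM mask elsewhere is pure leak and is cut at the ILM itself. The
region is clipped analogously at the RPE plane, and the component
containing the region centroid is kept. A one-sided clamp keeps the cap
within three voxels of the membrane, which also makes the operation
exactly idempotent: a second cut finds nothing above the membrane and
returns its input.

## Morphometry

All measurements run on the flattened mask. Each Y level intersecting the
mask yields one RPE-parallel section, measured on its largest connected
in-plane component: area (pixel count x `dx dz`), minimum/maximum Feret
diameters by rotating calipers on the convex hull of the pixel *corner*
points (a single pixel therefore has non-zero extent), centroid, and
meridians. The MA is the minimal-area section at heights within 20--90%
of the hole height, ties broken towards the RPE; the base section is the
lowest retained section (flagged if it sits more than two voxels above
the RPE -- a hole that is not full thickness); the top section is the
highest. Hole height runs from the RPE level to the highest mask voxel;
retinal height is the maximal ILM elevation over the rim ring (three
pixels wide) around the base footprint. Volume is voxel count times voxel
volume. Surface area triangulates the 0.5 iso-surface of the lightly
smoothed mask by marching tetrahedra with physical vertex coordinates.
The smoothing default, 0.7 voxels per axis, sits where the two
discretisation biases cancel: an unsmoothed binary surface is inflated by
its staircase, an over-smoothed one shrinks at curved and cornered
regions. At that setting digitised spheres, cubes and cylinders at 5 µm
isotropic spacing are reproduced to within a few percent, which the test
suite checks against the closed forms.

Two measurement details deserve their own justification:

* **Meridians from second moments.** Reported section meridians come from
  the principal axes of the pixel region (second central moments,
  including the per-pixel rectangle term), averaged over the nearest
  sections with area weights using the doubled-angle method for axial
  data. For ellipse-like sections the principal axis coincides with the
  maximum-Feret direction, but it is far more stable: on a *perfect*
  raster at the package's 25 µm z-pitch, the caliper meridian of a
  mildly eccentric section (axis ratio 1.15) is uncertain by almost 5°,
  dropping below 2° only at ratios of about 1.3 and above. Moment-based
  orientation uses every pixel and stays within ~2° down to small, coarse
  sections. `feret_diameters()` itself still reports caliper angles,
  matching the fine-step rotation oracle on polygons.
* **When is a meridian meaningful at all?** If the base, waist and top of
  a hole have different meridians, the meridian rotates along height, and
  on a near-flat area profile the minimum-area height itself is weakly
  determined -- two equally good MA choices can carry meridians tens of
  degrees apart. Recovery of meridians is therefore asserted on phantoms
  whose cross-sections share one rigid rotation and are distinctly
  elliptical (truth axis ratio &ge; 1.3); diameters, areas, volumes and
  misalignment are asserted on freely rotated phantoms too.

The IVTS class uses the published edges with a declared convention for
the unassigned boundary value: 250 µm classifies as small, 400 µm as
medium. The frustum ("truncated cone") volume
$V = \pi h (d_1^2 + d_1 d_2 + d_2^2)/12$ from MLD, BD and height is
provided as the 2D-calliper surrogate against which the voxel volume can
be compared.

## The phantom generator

`phantom_spec()` describes a three-band volume (vitreous, retina, bright
RPE band over a dimmer base) containing a parametric hole: three
elliptical cross-sections -- base, waist, top -- swept with
piecewise-linear interpolation of semi-axes and meridian (shorter arc,
mod 180°) and a linear lateral drift of the centre from base to top
("tilt"). This is the smallest family that reproduces the asymmetries the
3D analysis is designed to measure: distinct minimum/maximum diameters at
BA and MA, meridian rotation, and a misaligned centre line. Speckle is
multiplicative Gamma noise with unit mean and spread `s`; an optional
operculum (a floating tissue blob above the hole) can be rendered without
entering the ground truth. `analytic_truth()` computes every report field
from the spec, not the raster: closed forms where they exist (ellipse
area and Feret diameters, misalignment), 1 µm-step quadrature along
height for volume and the minimum-area search, and a fine height-angle
mesh for the lateral surface.

Defaults mirror the clinical protocol (768x496x49 at 5.47/3.87/30 µm,
cohort-scale hole dimensions, small speckle -- the protocol averages 16
frames per line, which suppresses most speckle). The test suite and the
acceptance script run desk-scale phantoms of 120x96x25--27 voxels at
(10, 5, 25) µm with hole diameters of 200--550 µm and 5% speckle: large
enough that every parameter is resolved, small enough that an end-to-end
segmentation takes ~15 s. What passing these tests shows is that the
pipeline recovers known geometry through realistic band structure,
anisotropy and speckle; what it cannot show is robustness to real-data
effects the phantom omits -- retinal sublayers, vessel shadows, motion
between B-scans, irregular membranes, operculum-adjacent boundaries.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(nx = 120, ny = 96, nz = 25,
                     spacing = voxel_spacing(10, 5, 25),
                     ilm_um = 100, rpe_um = 400,
                     base = c(250, 210, 20), waist = c(150, 120, 10),
                     top = c(180, 150, 30), waist_frac = 0.5,
                     tilt_um = c(60, 40))
ph <- generate_phantom(spec)
fit <- macular_hole(ph$volume)
print(fit)
dice(fit$mask, ph$truth)          # ~0.99 on this noiseless phantom
coef(fit)[c("ma_min", "ma_max", "ba_min", "ba_max")]
plot(fit)
```

## Agreement statistics

The comparison layer mirrors how automated and human measurements are
related in practice. `bland_altman()` reports the mean difference
(`a - b`; the sign convention travels with the output), the limits of
agreement mean ± 1.96 sd, and t-based confidence intervals -- standard
error $s/\sqrt n$ for the mean and the classical $s\sqrt{3/n}$
approximation for each limit, with $n-1$ degrees of freedom.
`spearman_assoc()` and `normality_test()` delegate to the standard
mid-rank Spearman and Shapiro--Wilk implementations.
`quad_vs_linear()` compares nested least-squares fits with the F test on
the squared term. `size_crosstab()` cross-tabulates two IVTS
classifications, counts reclassified cases and tests marginal homogeneity
with the Stuart--Maxwell statistic (chi-squared, $K-1$ df; identical
classifications give p = 1 by convention) -- a declared choice, since
reclassification tests are rarely named in applied reports.

## Known limitations

* The surface detectors assume one dominant bright band per column;
  pathology that disrupts the RPE (drusen, atrophy) needs a different
  detector behind the same interface.
* The ILM grey-opening window must exceed the hole-opening radius; very
  large holes need `opening_um` raised accordingly.
* Whole-voxel flattening quantises the base plane to one voxel; base
  diameters inherit that uncertainty (well inside the stated recovery
  tolerances at the tested spacings).
* The phantom's two-segment shape family cannot represent non-convex
  sections or overhanging walls; the morphometry itself measures
  whatever mask it is given, but recovery guarantees are only
  demonstrated within the family.
* Runtime scales linearly in voxels; clinical-resolution volumes
  (~19M voxels) take correspondingly longer than the desk-scale
  phantoms. The multiscale schedule and band cropping do most of the
  work of keeping that practical.
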