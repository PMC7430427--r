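# holemorph

Automated three-dimensional segmentation and morphometry of full-thickness
macular holes in SD-OCT volumes.

Macular holes are graded by size — small (≤250 µm), medium (250–400 µm),
large (>400 µm) — and size predicts both surgical success and the choice of
treatment. The conventional measurement is a clinician's calliper on a
single horizontal B-scan, which assumes the hole is symmetric and centred
on that scan. Real holes are oval, tilted, and narrowest roughly
perpendicular to the scan direction. `holemorph` measures the hole as the
3D object it is:

* **Segmentation** — a multiscale 3D level set under a local Gaussian
  distribution fitting (LGDF) energy: at every voxel the interior and
  exterior intensities are modelled by local Gaussians estimated in a
  physical-scale window, so the interface tracks the hypo-reflective hole
  through noise and anisotropy. Evolution is energy-monotone by
  construction (trial steps that increase the discrete energy are rejected
  and retried smaller).
* **Curvature-based surface cut** — the hole and the vitreous are equally
  dark and contiguous through the opening; the cut finds the
  high-curvature rim ring where the region crosses the ILM, spans a cap
  across the rim, and clips analogously at the RPE, leaving the closed
  hole-only mask.
* **Morphometry** — RPE-parallel sections in the flattened frame; minimum
  and maximum Feret diameters (rotating calipers on pixel-corner convex
  hulls) and meridians of the base area (BA) and of the minimum area (MA,
  the smallest section in the central 20–90% of the hole height); hole and
  retinal heights; surface area (marching-tetrahedra iso-surface, caps
  included); voxel volume; centre-line misalignment; the IVTS size class;
  and the clinician's truncated-cone volume surrogate
  `V = πh(d₁² + d₁d₂ + d₂²)/12`.
* **Agreement statistics** — Bland–Altman limits of agreement
  `mean(d) ± 1.96·sd(d)` with t-based confidence intervals, Spearman
  correlation, Shapiro–Wilk normality, quadratic-vs-linear nested-model
  comparison, and Stuart–Maxwell marginal homogeneity for IVTS
  reclassification tables.
* **Phantom generator** — synthetic OCT volumes (vitreous/retina/RPE
  bands, parametric hole swept between base, waist and top ellipses with
  meridian rotation and tilt, Gamma speckle) with *analytic* ground truth
  for every reported parameter, so the whole pipeline is testable without
  clinical data.

## Worked example

```r
library(holemorph)

# a synthetic hole: base 500x420 um at 20 deg, waist 300x240 um, tilted
spec <- phantom_spec(nx = 120, ny = 96, nz = 25,
                     spacing = voxel_spacing(10, 5, 25),
                     ilm_um = 100, rpe_um = 400,
                     base = c(250, 210, 20), waist = c(150, 120, 10),
                     top = c(180, 150, 30), waist_frac = 0.5,
                     tilt_um = c(60, 40))
ph  <- generate_phantom(spec)
fit <- macular_hole(ph$volume)    # surfaces -> flatten -> segment -> cut -> measure
print(fit)
#> Automated 3D macular hole segmentation
#>   volume 'phantom_seed1': 120 x 96 x 25 voxels @ (10, 5, 25) um
#>   level-set iterations: 43@1/4, 57@1/2, 82@1/1
#> Macular hole morphometry ('phantom_seed1')
#>   MA   309.2 x  250.0 um @  10.1 / 100.1 deg, height 155.0 um
#>   BA   506.1 x  425.0 um @  20.9 / 110.9 deg
#>   hole height 300.0 um; retinal height 290.0 um
#>   surface area 0.599 mm^2; volume 25.875 x10^-3 mm^3
#>   centre misalignment 67.2 um; horizontal MA diameter 300.0 um
#>   IVTS class: small

dice(fit$mask, ph$truth)          # overlap with the exact truth mask
#> [1] 0.9918306
print(ph$truth_params)            # analytic truth: MA 300x240 @ 10/100 deg,
                                  # BA 500x420 @ 20/110, height 300 um,
                                  # misalignment 72 um
```

The minimum-area section is recovered to within a voxel or two (309.2 vs
300 µm), its meridian to a fraction of a degree, the base diameters to
~6 µm, the hole height exactly, the centre-line misalignment to ~5 µm,
and the voxel volume and iso-surface area to within a few percent of the
analytic values.

For real exports, point `macular_hole()` (or `run_pipeline()`, which also
writes reports, masks and a run manifest) at a folder of uncompressed
grayscale TIFF B-scans with a `metadata.txt` sidecar giving `dx_um`,
`dy_um`, `dz_um`. A thin command-line front end with `run`, `segment`,
`measure`, `phantom` and `compare` subcommands is installed at
`inst/cli/holemorph.R`.

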