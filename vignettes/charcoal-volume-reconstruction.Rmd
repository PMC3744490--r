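---
title: "Quantifying charcoal as volume: 3D reconstruction from reflectance confocal z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying charcoal as volume: 3D reconstruction from reflectance confocal z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(charstack3d)
```

## The problem

Sedimentary charcoal is the standard proxy for past fire activity, and it
is usually quantified by *counting* particles on palynological slides. A
count, however, confounds fire signal with fragmentation: one large
particle broken into ten small ones produces ten times the "charcoal"
under a count-based proxy. Because charcoal is opaque and strongly
reflective, a confocal microscope operated in reflected-light mode can
optically section slide-mounted particles, producing a z-stack from which
each particle's three-dimensional shape — and therefore its *volume* —
can be reconstructed. Total charcoal volume (particle count times median
particle volume) is a fragmentation-robust abundance measure, and the two
proxies can rank the same pair of samples in opposite order.

`charstack3d` implements that workflow end to end: stack input with
explicit physical voxel spacing, thresholding and particle filtering, 3D
connected-component labeling, watertight surface extraction with volume /
surface-area / triangle-count statistics, per-particle shape morphometrics,
assemblage-level statistics, and a ground-truthed synthetic-stack
generator used to validate every step.

## Data model and conventions

* Stacks are arrays in `(z, y, x)` order; the voxel with 0-based index
  `(iz, iy, ix)` sits at physical position `(ix·dx, iy·dy, iz·dz)` µm
  (voxel-centre convention). Anisotropy is the norm — the z step is set by
  the focus drive, not the detector — and the two acquisition presets are
  `spacing_mesofossil()` (2.768 × 2.768 × 5.0 µm, 10× objective) and
  `spacing_microfossil()` (0.526 × 0.526 × 1.060 µm, 20×). Spacing always
  comes from the configuration, never from vendor TIFF tags, which are
  fragile and out of scope.
* Voxel-level quantities are reported in µm, µm² and µm³; assemblage
  totals in mm³ (1 mm³ = 10⁹ µm³).
* Per-particle records share one fixed CSV column order with units in the
  column names.

## Segmentation

Particles are bright on a dark background, so a voxel is foreground iff
its intensity is ≥ the threshold. The automatic threshold maximises the
between-class variance of the two-class intensity histogram (Otsu's
criterion) and records the value used; a fixed numeric threshold can be
given instead. "Smoothing" here means *small-object removal*
(`min_voxels`, and optionally a minimum projected area in µm²), not
blurring: isolated bright voxels are noise, and no upper size limit is
applied. Components are labeled in 3D under configurable 6/18/26
connectivity (default 26: compact fragments read as continuous to the
eye under diagonal adjacency). Labels are assigned in deterministic
raster-scan discovery order — row-major across the x–y field of view,
depth last — so `select_n_particles()` reproduces a "first n particles
along a transect" protocol deterministically.

Particles touching a stack face are handled by policy: `flag` (default;
keep but mark, preserving auditability), `keep`, or `drop`. Very thick
particles can reflect off the slide and paint a bright sheet on the
deepest focal plane; `suppress_bottom_reflection()` deletes the deepest
n slices. The default is 0 slices — the artifact matters only for
oversized particles, not for material in the normal slide-mounted size
range.

## Surface reconstruction and its numerical choices

Each particle's binary indicator is cropped, zero-padded (so surfaces
close even at stack borders), and triangulated at the 0.5 level by
marching tetrahedra on the Kuhn 6-tetrahedron subdivision of each grid
cell, with the anisotropic spacing applied *during* triangulation.
Vertices on shared cell edges are welded exactly, so the mesh is
watertight by construction; `mesh_statistics()` still verifies that every
edge is shared by exactly two triangles and rejects open meshes. Surface
area is the sum of triangle areas; enclosed volume is the absolute sum of
signed tetrahedra against the origin (divergence theorem), hence
translation-invariant.

Two numerical choices matter:

* **Default light smoothing.** A raw binary isosurface is exact in
  enclosed volume for axis-aligned faces but carries staircase facets
  that overestimate the area of curved surfaces substantially (a
  digitized ball of radius 15 voxels comes out ~27% high). The field is
  therefore smoothed with a small separable Gaussian (σ = 0.85 voxels per
  axis, calibrated on digitized spheres) before extraction: sphere area
  error drops below 1% and volume error stays near 1%. `smooth_sigma = 0`
  restores raw extraction.
* **Thin-structure fallback.** Structures only one or two voxels thick
  nearly vanish under smoothing (their smoothed field never reaches the
  0.5 level). When the maximum smoothed value inside a particle falls
  below 0.6 the raw binary field is used for that particle instead — raw
  marching is exact for thin axis-aligned slabs, where smoothing would
  underestimate volume catastrophically. The same logic applies to the
  2D outline used for circularity.

The voxel-count volume (`voxel_volume_oracle()`: count × dx·dy·dz) is
kept as an independent estimate alongside the mesh volume; the two agree
within 10% for particles of ≥ 100 voxels and converge as particles grow.
The mesh value is the primary one reported as `volume_um3`.

## Morphometrics

* **Projected area**: union of the particle's voxel columns over z times
  dx·dy — what a 2D transmitted-light measurement would see.
* **Bounding box (L, W, D)**: axis-aligned extents (index span + 1 voxel,
  × spacing), L ≥ W in-plane, D axial. Axis-aligned (not oriented)
  because manual measurements are made on screen axes; in-plane rotation
  of an elongated particle therefore changes L and W, which is
  documented behaviour.
* **Manual volume estimate**: L·W·D, the crude at-the-microscope box
  estimate. It always bounds the mesh volume from above; across real
  bonfire particles the overestimate factor runs ~2.4–3.9.
* **Ellipsoid-equivalent semi-axes**: eigenvalues λ₁ ≥ λ₂ ≥ λ₃ of the
  voxel-coordinate covariance (physical µm, uniform weights) give
  semi-axes √(5λ) — the uniform ellipsoid with the same second moments.
  Coplanar/collinear particles are clamped to half a voxel on the
  degenerate axes and flagged rather than erroring.
* **Shape class**: with tolerance τ (default 0.2), `sphere` if both
  (a−b)/a and (b−c)/b < τ, `oblate` if only the first, `prolate` if only
  the second, else `triaxial`.
* **Circularity**: 4πA/P² on the x–y projection, with P from
  linear-interpolated marching squares on a lightly smoothed outline
  (raw binary contours inflate P by ~4%, which would push even a perfect
  disc visibly below 1). Discretisation can leave values marginally
  above 1 for large near-circular outlines.
* **Aspect ratio**: L/W ≥ 1.

"Surface area" is genuinely ambiguous between total mesh area and 2D
projected area in this workflow's vocabulary; both are computed as
separate columns. Assemblage statistics use mesh area by default
(`area_metric = "projected"` switches), which is also the scale on which
the area-to-volume factor of ~13 µm arises: for thin plates
V ≈ (t/2)·A_mesh, so a 13 µm factor corresponds to plates ~26 µm thick.

## Assemblage statistics

`summarize_assemblage()` reports n, mean, median, standard error
(SD/√n), min and max for volume and area. `estimate_total_volume()`
multiplies particle count by median particle volume at full floating
precision and converts to mm³ — feeding back display-rounded mm³ medians
corrupts the 4th decimal of the total, which is why medians are carried
in µm³. The median (not the mean) is the default multiplier because
charcoal volume distributions are heavy-tailed; the mean-based total is
also written to the summary JSON for sensitivity.

`area_volume_regression()` fits volume against area by OLS, with a free
intercept by default (the calibration line and the y = 13x conversion
line are different objects); the through-origin fit is always reported
alongside, with r² defined about the origin-constrained model
(1 − RSS/Σy²). `compare_groups()` wraps the tie-corrected Kruskal–Wallis
rank test (chi-square approximation, groups − 1 df), returning H, p and
log₁₀p (finite even when p underflows); all-tied input returns H = 0,
p = 1. No multiple-testing correction is applied. "Size sorting" has no
canonical formula in this literature, so two standard scale-free
dispersion metrics are reported rather than one invented composite: the
coefficient of variation and the quartile coefficient of dispersion —
lower is better sorted.

## The synthetic generator: what it emulates and what it does not

`generate_assemblage()` renders sparse, non-touching, predominantly
oblate solid ellipsoids, bright on a dark background, into an
anisotropic, depth-limited stack with Gaussian noise — the geometry and
contrast of a mesofossil charcoal slide in reflectance mode. Defaults
are matched to a Cretaceous-mesofossil-like sample:

* spacing (2.768, 2.768, 5.0) µm; stack depth 150 µm (slide preparations
  run roughly 40–215 µm); 100 particles;
* lognormal volumes, median 1 227 426 µm³, σ_log 0.8 (a mean/median
  ratio of ~1.35, as observed, implies σ ≈ 0.78);
* semi-axis ratios b/a ∈ [0.85, 1] and c/b ∈ [0.15, 0.5]: flattened
  spheres with near-circular plan;
* orientation `"flat"` (random in-plane rotation only): platy particles
  settle flat when mounted. `"random"` (full 3D rotations) and
  `"axis-aligned"` are available;
* foreground/background 200/10 on 8 bits, noise SD 5;
* the x–y field auto-sizes so particle bounding boxes occupy ≤ 30% of
  the stack area; placement is largest-first rejection sampling of
  disjoint one-voxel-padded bounding boxes, so rendered particles can
  never touch even under 26-connectivity, and generation fails loudly
  (with the achieved count) rather than degrade;
* volume draws whose particle would be thicker than the stack are
  redrawn — the lognormal is truncated to particles that physically fit
  the preparation, exactly as on a real slide.

Ground truth per particle: centre, semi-axes, analytic volume (4/3·πabc)
and analytic surface area by Thomsen's approximation (p = 1.6075, max
error ~1.06%, which is folded into the tolerances used against it).

Fidelity limits, stated plainly: particles are smooth convex ellipsoids,
not fractured irregular solids; there is no optical model (no
point-spread function, depth attenuation, or speckle); noise is i.i.d.
Gaussian. Passing the validation suite therefore demonstrates that the
measurement chain is correct for well-separated convex particles under
realistic sampling and noise — it does not certify accuracy for
concave, porous or touching particles on real slides.

One estimator property worth knowing: for lognormal volumes the
count × median total systematically *underestimates* the summed true
volume by a factor e^{−σ²/2} (≈ −27% at σ_log = 0.8, ≈ −12% at 0.5),
because the median ignores the heavy tail that dominates the sum. The
test suite asserts this bias and its growth with σ. The estimate remains
the right comparative statistic across samples of similar spread, which
is how it is used.

## Problem sizes and validation design

The validation suite works at three scales, chosen as the smallest
problems that exercise each property: digitized spheres of radius 5–20
voxels against closed forms (volume within 2%, area within 3%, at
isotropic and 2:1 anisotropic spacing); uniform-thickness 26 µm discs of
radius 150–460 µm for the thin-slab identity V = (t/2)·A_mesh, whose
through-origin slope lands within 10% of 13 µm (the identity carries an
edge-band correction of order t/R, so the slope approaches 13 only for
footprints much wider than the thickness); and one full 100-particle
assemblage at the default conditions above, on which the complete
pipeline recovers per-particle volume with a median absolute relative
error well under 5% and classifies >90% of strongly oblate particles
(truth (b−c)/b ≥ 0.4) as oblate. Kruskal–Wallis output is checked
against explicit rank-sum enumeration over all two-group splits of eight
distinct values.

## Worked example

```{r example, eval = FALSE}
library(charstack3d)

# simulate a small assemblage (coarse voxels keep this quick)
g <- generate_assemblage(generator_params(
  n_particles = 10, spacing = voxel_spacing(10, 10, 10),
  volume_median_um3 = 1e6, depth_um = 300, seed = 11))

mask <- binarize(g$stack, "auto")
lab  <- filter_particles(label_particles(mask), min_voxels = 5)
rec  <- measure_all_particles(lab)
summarize_assemblage(rec, "demo")
estimate_total_volume(nrow(rec), median(rec$volume_um3))
```

The same chain, file-to-file with a manifest, is `run_pipeline()`, and
`exec/charstack3d` exposes `run`, `simulate` and `compare` subcommands
for shell use.

## Known limitations

* Thresholding cannot distinguish charcoal from other opaque reflective
  particles; that separation must happen at slide preparation.
* Touching particles are not split (no watershed): the imaged material
  is assumed dispersed, as mounted preparations are.
* Axis-aligned bounding boxes overestimate L and W for elongated
  particles lying diagonal to the image axes.
* Vendor microscope formats (CZI/LSM) are not parsed; stacks must be
  exported as multi-page grayscale TIFF and the spacing supplied
  explicitly.
* The area→volume factor of 13 µm is a property of thin oblate charcoal
  in these size fractions; it will not transfer to thick, blocky
  macrofossil material, and `predict_volume_from_area()` exposes k for
  exactly that reason.
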