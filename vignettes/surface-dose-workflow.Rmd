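---
title: "From scanned surfaces to 3D IOERT dose: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From scanned surfaces to 3D IOERT dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfdose)
```

## The problem

In intraoperative electron radiation therapy (IOERT) a single high dose of
electrons is delivered to a tumour bed during surgery through a cylindrical
applicator. Conventional dosimetry assumes water-equivalent tissue starting
at the applicator end — a flat irradiation surface. Real tumour beds are
irregular, sit below the applicator with an air gap, and may pool fluid, all
of which reshape the dose distribution. `surfdose` implements the full chain
needed to use a 3D surface scan of the surgical field instead of that flat
assumption:

1. reconstruct a triangle mesh from a scanned point cloud
   (`reconstruct_surface()`),
2. register it to a reference CT through fiducial markers
   (`fit_rigid_landmarks()`),
3. close it into a watertight solid (`extract_boundary_contour()`,
   `extrude_and_cap()`),
4. voxelize it and emit a two-valued air/water pseudo-CT
   (`voxelize()`, `correct_lid_region()`, `to_pseudo_ct()`),
5. compute an electron dose distribution on it (`compute_dose()`), and
6. compare dose distributions with a 3D gamma index (`gamma_map()`,
   `pass_rate()`).

A seeded phantom generator (`make_surgical_field()`, `place_markers()`,
`simulate_scan()`, `simulate_mesh_scan()`) provides every physical input of
the workflow synthetically, so the whole pipeline is exercised end-to-end by
`run_experiment()` without any measured data.

## Coordinate and grid conventions

All coordinates are physical millimetres in a single right-handed frame.
Volumes (`volume_image`) are axis-aligned with per-axis spacing and a
voxel-center origin: `origin` is the center of the first voxel, and a voxel
at index `(i, j, k)` (1-based) has center `origin + (i-1, j-1, k-1) *
spacing`. No direction-cosine matrices are carried; nothing in the workflow
rotates grids. Trilinear interpolation treats a volume as supported on
`[origin - spacing/2, origin + (dim - 1/2) * spacing]`, clamping the
outermost half voxel.

## Surface reconstruction

Single-viewpoint scans of a surgical field have height-map topology: the
surface is a graph over the plane orthogonal to the mean viewing direction
(overhangs cannot be scanned from one viewpoint in the first place).
`reconstruct_surface()` exploits this: it builds a moving-least-squares
(MLS) height field on a regular grid in the plane orthogonal to the cloud's
mean normal and triangulates it. The Gaussian kernel bandwidth is
`smoothing * max(grid_spacing, median point spacing)`, so refining the grid
on a dense noiseless cloud converges to the true surface, while on a noisy
cloud the kernel averages the range noise away. Grid nodes with no point
inside the support radius are dropped, which trims the mesh to the scanned
region and keeps occluded holes open rather than hallucinating geometry.

This choice replaces implicit-surface reconstruction (screened Poisson)
because, for the supported geometry class, the graph reconstruction is exact
in the noiseless limit, has one interpretable smoothing parameter, and never
produces spurious far-field sheets that would have to be trimmed
heuristically. Its price is the height-map restriction, stated above as an
explicit assumption. The reconstruction error is reported as the
point-surface error (PSE): the RMS distance from the input points to the
reconstructed mesh (`point_surface_rmse()`).

`denoise_cloud()` applies the standard k-nearest-neighbour statistical
outlier filter (reject points whose mean neighbour distance exceeds
`mean + std_ratio * sd`); `estimate_normals()` uses the smallest eigenvector
of the local k-neighbourhood covariance, oriented towards the scanner.

## Watertight closure and voxelization

An open scan cannot be voxelized by parity counting, so it is closed the way
an operator would in mesh software: take the longest boundary loop
(optionally inset by `offset` mm, trimming the rim), raise vertical walls to
a planar lid above the highest surface point, and cap the lid. The lid is
triangulated as a planar fan about the loop centroid, which is robust for
any simple loop (collinear runs along straight boundaries produce no
degenerate triangles) and pairs every wall edge exactly once. Small interior
occlusion holes are closed by the same fan construction; stray disconnected
islands (for instance marker patches separated by rim trimming) are dropped,
keeping the largest connected component — the surgical field. Faces carry
tags (`scan`, `wall`, `lid`) through PLY I/O.

`voxelize()` marks a voxel as inside when a vertical ray through its center
crosses the solid an odd number of times. Degenerate hits (rays through a
vertex or edge) are resolved by deterministically jittering the ray origin
by 1e-4 voxel towards the mesh interior until the hit is clean; jittering
towards the interior matters because a jitter off the outer boundary would
be accepted as a clean miss. The extruded solid encloses the *air gap*
between the surface and the lid, not the tissue; `correct_lid_region()`
therefore rewrites the binary volume so a voxel is 1 exactly when its
center lies below the scan-tagged surface of its column. This reproduces the
intended semantics — the artificial closure volume returns to air, tissue
remains — and is exact at the voxel level: extracting the -500 HU isosurface
of a two-valued volume (`surface_from_volume()`, column-wise linear
interpolation places the crossing halfway between the last tissue and first
air voxel centers) and re-voxelizing on the same lattice reproduces the
tissue mask voxel-for-voxel. The round-trip acceptance check below relies on
this.

`to_pseudo_ct()` then maps 1 to water (0 HU) and 0 to air (-1000 HU),
enlarging the matrix by a configurable padding (default 20 voxels per face):
padded voxels below the grid continue their column (water below tissue),
all other padding is air. `ct_to_tissue_air()` produces the same two-valued
study from a real CT by thresholding air at -500 HU (parameter `air_max`).

## Registration

Landmark rigid registration uses the closed-form SVD solution with the
standard reflection guard, and reports the fiducial registration error
(FRE), the RMS landmark misfit after alignment. Under isotropic per-axis
landmark noise sigma on N markers, theory predicts an expected FRE of
`sigma * sqrt(3 (1 - 2/N))`; the test suite verifies this with Monte Carlo
at N = 6, sigma = 0.5 mm. Surface accuracy at targets away from the
fiducials is quantified by `mesh_tre()`: RMS and maximum vertex-to-surface
distance between the registered scan and the surface derived from the
reference CT. Because scanned meshes are not in vertex correspondence with
CT-derived meshes, vertex-to-surface distance is the only well-defined
reading; nearest-vertex distance is available as `mode = "vertex"`.

Marker positions are picked as intensity-weighted centroids above an HU
threshold inside a seed sphere on the CT side (`landmark_from_ct()`), and as
vertex centroids within a small radius on the scan side
(`landmark_from_surface()`). The scan side sees the marker *surface*, not
its center, so a common half-diameter bias of ~0.5 mm enters the scan-side
landmarks; it is absorbed almost entirely by the registration translation
and surfaces only as a small TRE contribution, as it would with manual
marker picking.

## The dose engine

The dose engine is a deterministic broad-beam model, built as a documented
stand-in for a Monte Carlo treatment planning system: every acceptance-level
comparison in this package is engine-to-engine (the same engine run on
different CT inputs), so the stand-in's absolute accuracy never enters the
comparisons — what matters is that it responds to surfaces, air gaps and
densities the way electron dosimetry does.

For a voxel at position p:

* **Depth.** The geometric depth is measured along the beam axis from the
  (beveled) applicator end plane. The radiological depth is the line
  integral of physical density over that segment, sampled every 0.2 mm with
  trilinear interpolation (`radiological_depth()`). Densities come from a
  piecewise-linear HU map anchored at air (-1000 HU, 0.0012 g/cm3), water
  (0 HU, 1.0) and +1000 HU (1.6) (`hu_to_density()`).
* **Depth dose.** A monotone-spline percentage-depth-dose (PDD) curve rises
  from `surface_dose` (default 0.85) to 1.0 at `R100`, falls through 0.5 at
  `R50`, reaches ~2% at the practical range `Rp` and decays to a 0.2%
  bremsstrahlung floor. Defaults (R100 20 mm, R50 36 mm, Rp 45 mm)
  are representative clinical-order values for a 9 MeV beam and are fully
  configurable; the engine's calibration contract does not depend on them.
* **Lateral profile.** Flat inside the geometric field (the applicator
  circle, projected along rays diverging from a virtual source at the
  calibration SSD, default 1000 mm), Gaussian penumbra of width
  `penumbra_sigma` (default 4 mm) at the edge, and a 1% scatter tail with
  10 mm Gaussian decay outside. The bevel tilts the end plane (and with it
  the depth origin), not the projected aperture.
* **Inverse square.** The factor `((SSD + tissue path) / (SSD + geometric
  depth))^2` is exactly 1 in the calibration geometry (surface at the end
  plane) and for any uniform medium filling the space beyond the plane, so
  uniform density scaling compresses the depth axis by exactly 1/rho; with
  an air gap g it reduces to the textbook gap factor
  `((SSD + d) / (SSD + g + d))^2`.

100% is the central-axis maximum in water with the surface at the applicator
end — `compute_dose()` on such a volume returns exactly 100 at R100 and 50
at R50 on the axis. `water_assumption_dose()` evaluates the engine on a
uniform water half-space bounded by the beveled end plane: the conventional
flat-surface assumption, independent of any patient CT.

Known limitations of the stand-in, by design: no lateral scatter
disequilibrium (a narrow air channel in tissue changes only the rays that
cross it), no obliquity correction of the penumbra, no output-factor or
absolute (Gy) dosimetry, no Monte Carlo noise — and consequently no analogue
of a Monte Carlo error tolerance.

## 3D gamma analysis

`gamma_map()` implements the global-normalisation gamma index: for each
reference voxel above the dose threshold and inside the tissue mask,

gamma = min over r of sqrt( (D_eval(r) - D_ref)^2 / dD^2 + |r - r_ref|^2 / dta^2 ),

with dD equal to `dose_diff_pct` percent of the normalisation dose — by
default the maximum of the reference distribution over the mask (an explicit
`norm_dose` can be supplied, e.g. the calibration 100%). The threshold is
applied to the reference dose; sub-threshold and out-of-mask voxels are
excluded from both numerator and denominator of `pass_rate()`. The search
runs over precomputed offsets within `search_radius` (default 3 x DTA, which
cannot be exceeded by any passing voxel) at step `search_step` (default
DTA/10), sorted by distance with early termination once the distance term
alone exceeds the current best — an exact optimisation of the same discrete
minimisation, verified against the plain exhaustive scan to 1e-6 in the test
suite. The evaluated dose is trilinearly interpolated, so the two
distributions may live on different commensurable grids
(`resample_to_grid()` handles explicit regridding, trilinear for continuous
data and nearest-neighbour for masks).

## The synthetic phantom

`make_surgical_field()` emulates the experiment's physical scene as a pure
function of its seed: a smooth random relief (coarse Gaussian noise,
bilinear upsampling, binomial smoothing; standard deviation `roughness`,
default 6 mm) over a `base_height` floor, with `n_holes` deep narrow
Gaussian depressions (default two holes, 20 mm deep, 14 mm wide — the
defining features that self-occlude under single-viewpoint scanning).
Tissue below the surface gets HU ~ N(40, 30) with optional -60 HU slabs so
that full-HU and two-valued inputs produce distinguishable doses; air above
is -1000 HU. An optional fluid level raises (flattens) all lower surface
points — the with-fluid configuration — and `blood_level_for_gap()` solves
for the level that produces a prescribed maximum air gap under a fixed
applicator. `place_applicator()` positions the beam so the maximum
end-plane-to-surface distance over the footprint matches the study value
(33.5 mm without fluid, 13.2 mm with fluid, both configurable).

Six 1 mm metallic markers sit on cuboid pedestals of different heights on a
ring outside the applicator footprint (`place_markers()`); the marker sphere
is rendered into the CT through a Gaussian point-spread blur (sigma
0.75 mm), which is how a sub-voxel metal fiducial actually appears in CT, and
the exact centers are returned as ground truth. The 1 mm isotropic phantom
lattice is the supported regime for marker localisation; at substantially
coarser voxels a 1 mm fiducial is genuinely sub-resolution.

`simulate_scan()` emulates a tracked range scanner: jittered-grid surface
samples (exact heights on the triangulated true surface), ray-cast occlusion
against the height map (deep narrow holes self-occlude exactly as a real
single-viewpoint scan), rejection of grazing incidence beyond
`max_incidence_deg`, and Gaussian range noise *along the view ray* (range
noise is what both device classes produce). `simulate_mesh_scan()` returns
the visible submesh with vertex range noise and closes small occlusion holes,
mimicking a structured-light scanner's post-processed mesh output. Default
noise levels — 1.5 mm for the point-cloud scanner and 0.3 mm for the
structured-light scanner — were chosen once to reproduce the observed orders
of magnitude (a ~2 mm PSE after reconstruction for the former; a sub-0.5 mm
resolution class device for the latter).

What the phantom does **not** model: CT metal artefacts, scanner radiometry
(laser signal strength, texture), overhanging anatomy, deformation between
scan and CT, and tracking drift. Passing tests therefore demonstrate the
correctness of the geometry/dose/gamma chain under the stated geometry
class, not robustness to those real-world effects.

## The scripted experiment

`run_experiment()` reproduces the full comparison design per configuration
(without and with fluid): reference dose on the full-HU CT; the flat-water
assumption; the two-valued tissue/air study; the two scanner-based
pseudo-CTs (the scans are taken in a seeded, rigidly displaced scanner frame
and registered back through the markers); and the round-trip pseudo-CT
rebuilt from the tissue/air study's own isosurface. Gamma runs at the 10%
and 70% thresholds with 3%/3 mm and the tissue mask, and the report (JSON +
CSV) carries PSE, FRE, TRE, stability RMSE and all pass rates. Two runs with
the same configuration and seed produce byte-identical reports.

```{r experiment, eval = FALSE}
cfg <- default_experiment_config(seed = 1)
report <- run_experiment(cfg, out_dir = "experiment_out")
report$pass_rates
```

The expected qualitative picture mirrors the physics: the round trip scores
100.0% at both thresholds (conversion fidelity), the tissue/air comparison
sits near 100% (heterogeneity at +/-60 HU barely moves electron dose), both
scanner-based doses score high, and the flat-water assumption scores clearly
lowest — it ignores a 33.5 mm (or 13.2 mm) air gap and the surface shape.

## Numerical choices and degenerate inputs

* Ray-degeneracy jitter: 1e-4 voxel, deterministic, interior-directed;
  voxelization is bitwise reproducible and translation-equivariant.
* Gamma search: radius 3 x DTA, step DTA/10 (both configurable); candidates
  outside the evaluated grid's support are skipped rather than filled.
* Dose marching step 0.2 mm; materials below 0.05 g/cm3 count as air for
  the tissue-path length in the inverse-square factor.
* Collinear landmark configurations and sub-3-marker sets are rejected;
  near-planar noisy sets are protected by the SVD reflection guard.
* Meshes are cleaned of zero-area faces on construction; `extrude_and_cap()`
  validates that the contour lies within 2 mm of the mesh and refuses
  non-watertight results rather than repairing silently.
* Degenerate scan inputs (empty visibility, all-outlier clouds, fewer than
  100 points) raise classed errors early with actionable messages.

## Problem sizes used in the checks

The package's own validation runs at desk scale, chosen once: the round-trip
fidelity check uses a 140-150 mm phantom at 1 mm isotropic (~3 M voxels);
gamma optimised-vs-exhaustive equivalence uses twenty 40^3 dose pairs at
3%/3 mm with a 9 mm search radius and 0.25 mm step; voxelizer parity uses
twenty random closed meshes (< 500 faces) against a winding-number oracle;
the registration Monte Carlo uses 100 noiseless and 1000 noisy trials; the
directional water-vs-surface comparison runs five seeds of a 90 mm phantom
with a 2 mm dose grid in both fluid configurations. The paper-scale
experiment (150 mm, 1 mm everywhere) runs in a few minutes through
`run_experiment()`.
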