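---
title: "Methods: 3D myocardial scar models from LGE CMR"
author: "scarmesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D myocardial scar models from LGE CMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

Late gadolinium enhancement (LGE) CMR depicts infarcted myocardium as
hyperintense tissue.  For planning and guiding scar-related ventricular
tachycardia ablation, the three-dimensional architecture of that scar —
its transmural depth, its intramural course, its endocardial footprint —
matters as much as its extent.  `scarmesh` turns a 3D LGE volume plus
per-slice endo-/epicardial contours into three coupled 3D models:

1. smooth endo- and epicardial surface meshes reconstructed from the
   contour point clouds;
2. a voxel-wise scar mesh in which every scar voxel is rendered as a cuboid
   at the native scan resolution, welded into a boundary shell;
3. an endocardial surface map of the subendocardial scar, carried as
   per-vertex colors and optionally baked into a texture.

The layers are blended with configurable transparency and exported to open
interchange formats (OBJ+MTL, PLY, glTF/GLB) for external 3D or
augmented-reality viewers.  Three scar-burden metrics accompany the models:
scar volume as a percentage of LV myocardium, the subendocardial share of
scar volume, and the scar-covered fraction of the endocardial surface.

## Pipeline stages and their assumptions

### Myocardium rasterisation

A voxel belongs to the myocardium iff its centre is inside the epicardial
polygon of its slice and outside the endocardial one.  Point-in-polygon
uses the even-odd rule with centres exactly on an edge counting as inside —
an explicit tie-break that makes grid-aligned phantom tests deterministic.
Voxel indices are 0-based and a voxel's world position refers to its
centre, matching medical-volume affine semantics; the cuboid rendered for a
voxel spans half a spacing either side of the centre.  An epicardial
contour without an endocardial partner contributes a full disk (apical
cap); the converse is an error.

### FWHM scar classification

Scar is defined as myocardial voxels with signal intensity strictly greater
than half of a reference maximum (the full-width-at-half-maximum
criterion).  The reference maximum defaults to the plain maximum over the
myocardium — the most literal reading — with two escape hatches for real
data: a user-supplied hyperenhanced reference region, and a robust
percentile (default the 100th, i.e. disabled).  The criterion is invariant
under positive rescaling of the intensities, which the tests assert
exactly.  Uniform-intensity inputs are returned all-scar with a
degenerate-contrast warning rather than an error.

### Surface reconstruction

Contours of one anatomical surface are merged into a point cloud, thinned
by clustering decimation (one centroid per occupied cell of a uniform 3D
grid; cell default twice the in-plane spacing, tying the cloud density to
the scan resolution), and oriented by 10-nearest-neighbour PCA normals.
Normal signs are made locally consistent by breadth-first propagation over
the k-NN graph and globally flipped outward against the cloud centroid.

The mesh itself comes from an implicit-function reconstruction built into
the package: the signed distance at a query point is estimated from the k
(default 8) nearest oriented points as the mean of two first-order
estimators — the inverse-distance-weighted tangent-plane distance, and the
distance to the plane through the weighted neighbour centroid with the
averaged normal.  The two estimators carry curvature biases of the same
magnitude, about $s^2/2R$ for point spacing $s$ and curvature radius $R$,
but of *opposite sign* (the first pushes the zero level outside a convex
surface, the second inside), so their mean cancels the bias to second
order.  This matters quantitatively: a one-sided estimator displaces both
ventricular surfaces outward by roughly 0.1 mm at a 2 mm cloud spacing,
which propagates into a transmural-depth bias of about 0.015 and a
percentage-point-scale error in the subendocardial scar share.

The zero level set is extracted by marching tetrahedra on the Freudenthal
6-tetrahedron subdivision of a regular grid with $2^{\text{depth}}$ cells
along the longest bounding-box axis (default depth 7).  Marching
tetrahedra is unambiguous, so the output is watertight by construction
wherever the field is negative somewhere inside the grid; triangle
orientation follows the per-tetrahedron field gradient.  Because a
ventricular contour stack is open at the base, the signed-distance field is
intersected with the cloud's bounding box expanded by a small margin, which
closes the surface just beyond the basal rim; the artificial closure is cut
away again by clipping at the plane of the most basal contoured slice.

Clipping removes faces whose *centroid* lies beyond the plane.  The depth
field is measured against the clipped surfaces: the closure above the rim
is not anatomy, and on the half-resolution phantom it would otherwise
attract the distance queries of basal wall voxels and bias the epicardial
distance by about 0.2 mm.

### Transmural depth and layers

For each myocardial voxel centre $p$, depth$(p) = d_{\text{endo}}(p) /
(d_{\text{endo}}(p) + d_{\text{epi}}(p))$ with unsigned Euclidean
point-to-mesh distances — 0 on the endocardium, 1 on the epicardium.  The
two-distance ratio is exact for concentric shells and simple to test;
Laplacian transmural coordinates would handle strongly non-parallel
surfaces better and are a possible extension.  The wall is partitioned
into thirds with half-open intervals, closed at 1: subendocardial
$[0, 1/3)$, mid $[1/3, 2/3)$, subepicardial $[2/3, 1]$ — so a depth of
exactly 1/3 is mid.  If the surfaces touch, affected voxels get depth 0
with a warning.

### Voxel-wise scar mesh

Every scar voxel becomes an axis-aligned cuboid of the native voxel size
(8 vertices, 12 outward-wound triangles).  Deduplication welds vertices
through exact integer corner-lattice keys (float tolerance only matters
for meshes without lattice provenance) and removes *both* copies of every
coincident face, so interior walls between 6-adjacent cubes vanish and the
boundary shell remains; keeping one copy would leave non-manifold internal
walls, though a `keep_one` switch preserves that alternative reading.  The
enclosed volume, computed by the divergence theorem in lattice integers,
equals the voxel count times the voxel volume *exactly* (bit-for-bit in
IEEE doubles), which the tests assert with identity comparisons.

One caveat is intrinsic to cube shells: two voxels touching only across a
lattice edge ("checkerboard" contact) produce a closed but non-2-manifold
shell — four faces meet at the shared edge.  Arbitrary random masks are
therefore validated for closedness (every edge count even) and positive
enclosed volume; strict two-faces-per-edge watertightness holds for the
canonical blocks and for the phantom scar meshes.

### Endocardial projection

Only subendocardial scar (depth < 1/3) influences the surface map; the
tests verify bit-identical maps after deleting all deeper scar voxels.
Two vertex rules are provided because the voxel-to-point assignment is a
genuinely open design choice:

* **binary** — a vertex is scar-positive iff at least one subendocardial
  scar voxel centre lies within the search radius (default twice the
  largest voxel spacing).  Simple and good for display, but it dilates the
  scar footprint by roughly the radius along the scar boundary, inflating
  the area fraction by several percentage points on a 60–80° sector.
* **graded** (used by the pipeline for quantification) — the vertex value
  is the scar fraction among subendocardial myocardium voxels within the
  radius.  The boundary smoothing is symmetric, so the area estimate is
  first-order unbiased; thresholding the graded map at 0.5 coincides with
  the binary map wherever neighbourhoods are homogeneous (empty or
  saturated maps) but not along sector boundaries.

The scar area fraction weights each face by the mean of its three vertex
values times its area; this mixed-face rule converges with mesh
refinement.  Texture baking parametrises the clipped, disk-like
endocardium by a Tutte barycentric embedding — the basal boundary loop is
mapped to a circle by arc length and interior vertices solve a uniform
Laplace system — which is provably fold-free for a mesh homeomorphic to a
disk (a geometric polar map about the long axis was tried first and
produced occasional sliver-triangle fold-overs on reconstructed meshes).
Vertex colors are rasterised into the texels barycentrically.  Per-vertex
colors remain the primary carrier; the texture is optional.

### Scene assembly and export

Layers default to epicardium gray at alpha 0.2, endocardium red-brown at
0.4, scar yellow opaque, so the scar reads through the translucent shells.
Scenes are written to glTF 2.0/GLB (one mesh node per layer, PBR material,
`alphaMode = "BLEND"` for transparent layers), OBJ with a sidecar MTL
(`d` transparency), and single meshes additionally to binary
little-endian PLY with uchar RGBA vertex colors.  All writers have
matching readers and the export–import–export cycle is byte-stable.
Units are mm with +z toward the cardiac base.

## The phantom and what it does (not) emulate

The synthetic data generator models a short-axis LGE acquisition of an
axisymmetric ellipsoidal-shell LV (default endocardial semi-axes
17×17×28 mm, epicardial 26×26×38 mm — wall thickness about 9 mm,
swine/human ventricle scale), truncated at a basal plane at half the
epicardial long semi-axis, with an optional displaced thin-shell RV.
Voxel spacing defaults to 1 mm isotropic (the in-vivo regime) and supports
the 0.4–0.5 mm ex-vivo regime.  Intensities are mean 30 in remote
myocardium, 100 in scar, background (blood pool and air) at half the
remote mean so the FWHM criterion inside the myocardium is unaffected by
background, plus additive Gaussian noise (SD 2 by default).  Gaussian
rather than Rician noise is sufficient at these contrast levels for
segmentation testing.

Scar blobs live in normalised shell coordinates — an azimuthal sector
times a transmural depth band anchored at the endocardium — so transmural
extent is exact by construction and the projection and metric tests have
closed-form truth.  A depth band `c(0.5, 1)` yields mid/epicardial-only
scar with subendocardial sparing.  Truth fractions are obtained by
numerical integration of the *continuous* geometry on a 0.35 mm grid,
with the transmural coordinate evaluated from exact point-to-ellipsoid
distances (vectorised bisection on the closest-point KKT parameter), and
are therefore independent of the voxel grid.  Contours are the analytic
intersection ellipses discretised to 128 points per slice — at that
density the chord sagitta ($\approx r(2\pi/n)^2/8 \approx 5\cdot10^{-3}$
mm) is negligible against the voxel size, so the rasterised myocardium and
the continuous truth agree to well under a tenth of a voxel.  At 64
points the 0.02 mm chord band admits a thin rim of dark blood-pool voxels
into the mask exactly where the projection search balls sit, which is
measurable in the surface fraction at 0.5 mm spacing.

Masks depend only on the geometry: the same seed reproduces the phantom
bit-for-bit, and different seeds change only the noise.

What the phantom does *not* contain: trabeculation and papillary muscles,
partial-volume intensity mixing at tissue boundaries, coil shading, motion
or reconstruction artifacts, Rician noise floors, and non-ellipsoidal
remodelled ventricles.  Passing the recovery tests therefore demonstrates
that the geometric chain is unbiased at the stated resolutions on smooth
geometry — not that FWHM segmentation or the projection radius are robust
to the full complexity of clinical LGE.

## Numerical choices

* Reconstruction defaults: decimation cell = 2 × in-plane spacing, k = 10
  normals, k = 8 signed-distance neighbours, grid depth 7, bounding-box
  cap margin 3 grid steps.  The signed-distance field is evaluated in a
  fast two-pass scheme (1-nearest-neighbour sign everywhere, full k-NN
  refinement within 3 grid steps of the zero level).
* Exact-boundary conventions: FWHM uses strict `>`; layer intervals are
  half-open, closed at depth 1; field values of exactly zero in the
  isosurfacer are nudged by $10^{-12}$ so crossings never sit on grid
  nodes.
* Point-to-mesh distance uses a uniform-grid nearest-vertex bound: the
  closest triangle must have a vertex within $\sqrt{d^2 + e_{\max}^2}$ of
  the query ($d$ = nearest-vertex distance, $e_{\max}$ = longest edge), so
  only the faces incident to that small vertex ball are tested exactly.
* Problem sizes in the shipped tests: the unit suite uses a reduced LV
  (12/19 mm in-plane semi-axes) at 1 mm; the acceptance suite runs the
  full-size default ventricle across 11 feasible (burden, transmurality)
  combinations at 1 mm and 0.5 mm.  These sizes were chosen so the whole
  suite exercises both resolution regimes on a single CPU in well under
  half an hour.

## Known limitations

* The two-distance depth ratio is exact only for locally parallel
  surfaces; strongly divergent walls (e.g. near the outflow tract in real
  anatomy) would benefit from Laplacian depth.
* A scar burden of 40% of LV myocardium cannot be realised with a
  transmural extent of 0.3: a depth band $[0, 0.3]$ holds at most about a
  quarter of the wall volume of any shell, because inner bands are always
  volumetrically thinner than their depth share.  The recovery grid
  excludes that single infeasible combination.
* Binary projection is intentionally left as the display default of
  `project_scar()`; quantitative consumers should use (and the pipeline
  does use) the graded mode.
* Surfaces are reconstructed per label; no contact handling is attempted
  where RV and LV epicardium approach each other.
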