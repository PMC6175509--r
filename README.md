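# scarmesh

3D models of myocardial scar from late gadolinium enhancement (LGE)
cardiovascular MRI, in R.

LGE imaging is the clinical gold standard for myocardial scar, and the 3D
architecture of that scar — transmural depth, intramural course,
endocardial footprint — is the substrate of re-entrant ventricular
tachycardia (VT).  `scarmesh` is for imaging scientists and
electrophysiology researchers who want to turn a segmented LGE scan into
explorable 3D models: it reconstructs smooth endo-/epicardial surface
meshes from per-slice contours, segments scar with the
full-width-at-half-maximum (FWHM) criterion, renders every scar voxel as a
cube at the native scan resolution, projects subendocardial scar onto the
endocardial surface, and exports the transparency-blended layers to open
formats (OBJ+MTL, PLY, glTF/GLB) that any 3D or augmented-reality viewer
can load.

## The models and metrics

Given an LGE volume $I$ and a myocardial mask $M$ from endo-/epicardial
contours:

* **FWHM scar**: $S = \{v \in M : I(v) > \tfrac12 \max_{w \in M} I(w)\}$.
* **Surfaces**: contour points → clustering decimation → 10-NN PCA
  normals → implicit-function reconstruction (signed-distance field from
  oriented tangent planes, marching-tetrahedra isosurface) → basal clip.
* **Transmural depth**: $\delta(v) = d_{endo}(v) / (d_{endo}(v) +
  d_{epi}(v))$, with subendo/mid/subepi layers at thirds of $\delta$.
* **Voxel-wise scar mesh**: one cuboid per scar voxel, duplicate vertices
  and faces removed so the watertight boundary shell remains; its enclosed
  volume equals $|S| \cdot d_x d_y d_z$ exactly.
* **Surface scar map**: vertices of the endocardial mesh marked (binary)
  or graded by the subendocardial scar ($\delta < 1/3$) within a search
  radius.
* **Metrics**: scar volume as % of LV myocardium ($100\,|S|/|M|$), the
  subendocardial portion of scar ($100\,|S \cap \delta < 1/3|/|S|$), and
  the scar-covered % of the endocardial surface area.

A synthetic phantom — an ellipsoidal-shell LV with azimuthal scar blobs of
exact transmural extent, analytic ground truth, and configurable voxel
spacing from the 1 mm in-vivo to the 0.4–0.5 mm ex-vivo regime — makes the
entire chain testable without patient data.

## Worked example

```r
library(scarmesh)

phantom <- generate_phantom(phantom_spec(seed = 1))   # 1 mm LGE + contours
model <- scar_pipeline(phantom$volume, phantom$contours)
print(model)
#> <scar_model>
#> <scar_segmentation> 7882 scar / 59726 myocardial voxels (13.2%), FWHM threshold 54.31
#>   scar mesh: 4704 vertices, 9404 faces, 7882 mm^3 in 1 component(s)
#> <scar_metrics>
#>   scar volume:             13.2 % of LV myocardium
#>   endocardial portion:     41.9 % of total scar
#>   surface-projected area:  21.0 % of endocardial surface

export_scene(model$scene, "scar_model.glb")           # epi / endo / scar layers
write_mesh(vertex_colors_from_map(model$surface_map), "endo_scar.ply")
```

Reading the output: the FWHM threshold is half the maximum myocardial
intensity (reference max ≈ 108.6 under noise, threshold 54.31); 7882 of
59726 myocardial voxels exceed it, i.e. a scar burden of 13.2% of the LV
wall.  The deduplicated voxel-wise scar mesh encloses exactly 7882 mm³ —
one mm³ per scar voxel at this resolution.  41.9% of the scar volume lies
in the subendocardial third of the wall, and the projected scar footprint
covers 21.0% of the endocardial surface.  The phantom's analytic truth for
this geometry is 13.2 / 41.8 / 20.8%, so the full measurement chain is
accurate to a fraction of a percentage point.

A thin command-line front end over the same functions ships in
`inst/cli/scarmesh.R`:

```sh
Rscript inst/cli/scarmesh.R phantom --out-prefix demo/case
Rscript inst/cli/scarmesh.R all --volume demo/case_lge.nii.gz \
    --contours demo/case_contours.json --out demo/scene.glb
```

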