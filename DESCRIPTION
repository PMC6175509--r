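Package: scarmesh
Title: Voxel-Wise 3D Myocardial Scar Meshes and Endocardial Scar
    Projection from LGE CMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds three-dimensional models of myocardial scar from late
    gadolinium enhancement (LGE) cardiovascular magnetic resonance.  From a
    3D LGE volume and per-slice endo-/epicardial contours it reconstructs
    smooth ventricular surface meshes from oriented contour point clouds,
    segments scar with the full-width-at-half-maximum (FWHM) criterion,
    renders every scar voxel as a cube at the native scan resolution with
    duplicate vertex/face removal, projects subendocardial scar onto the
    endocardial surface as per-vertex colors or a baked texture, assembles
    the layers into a transparency-blended scene exportable to OBJ, PLY and
    glTF/GLB, and reports scar-burden metrics.  A synthetic ellipsoidal-shell
    phantom with analytic ground truth makes the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    png,
    Matrix,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
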