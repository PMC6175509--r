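demo_scene <- function() {
  assemble_scene(endo = icosphere(8, subdivisions = 2),
                 epi = icosphere(12, subdivisions = 2),
                 scar_mesh = cube_mesh(center = c(9, 0, 0)))
}

test_that("the default style blends epi 0.2, endo 0.4, scar opaque", {
  sc <- demo_scene()
  expect_equal(vapply(sc$layers, function(l) l$name, ""),
               c("epicardium", "endocardium", "scar"))
  expect_equal(vapply(sc$layers, function(l) l$alpha, 0), c(0.2, 0.4, 1.0))
})

test_that("single-layer scenes are valid and duplicates are rejected", {
  sc <- assemble_scene(endo = icosphere(5, subdivisions = 1))
  expect_length(sc$layers, 1L)
  expect_error(add_layer(sc, "endocardium", cube_mesh()), "duplicate")
  expect_error(add_layer(sc, "halo", cube_mesh(), alpha = 1.5), "alpha")
  expect_error(assemble_scene(), "at least one layer")
})

test_that("style overrides pass through to the exported material", {
  style <- scene_style()
  style$endocardium$alpha <- 0.5
  sc <- assemble_scene(endo = icosphere(5, subdivisions = 1), style = style)
  path <- withr::local_tempfile(fileext = ".glb")
  export_scene(sc, path)
  back <- read_scene(path)
  expect_equal(back$layers[[1]]$alpha, 0.5, tolerance = 1e-9)
})

test_that("GLB export keeps one node per layer and flags blending", {
  sc <- demo_scene()
  path <- withr::local_tempfile(fileext = ".glb")
  export_scene(sc, path)
  raw_all <- readBin(path, "raw", file.info(path)$size)
  expect_identical(rawToChar(raw_all[1:4]), "glTF")
  jlen <- readBin(raw_all[13:16], "integer", size = 4, endian = "little")
  json <- jsonlite::fromJSON(rawToChar(raw_all[21:(20 + jlen)]),
                             simplifyVector = FALSE)
  expect_length(json$nodes, 3L)
  expect_length(json$meshes, 3L)
  modes <- vapply(json$materials, function(m) m$alphaMode, "")
  expect_equal(modes, c("BLEND", "BLEND", "OPAQUE"))
})

test_that("scene round-trips preserve counts, colours and alphas", {
  sc <- demo_scene()
  for (ext in c(".glb", ".gltf", ".obj")) {
    path <- withr::local_tempfile(fileext = ext)
    export_scene(sc, path)
    back <- read_scene(path)
    expect_length(back$layers, 3L)
    for (i in 1:3) {
      expect_equal(nrow(back$layers[[i]]$mesh$vertices),
                   nrow(sc$layers[[i]]$mesh$vertices), info = ext)
      expect_equal(nrow(back$layers[[i]]$mesh$faces),
                   nrow(sc$layers[[i]]$mesh$faces), info = ext)
      expect_equal(back$layers[[i]]$alpha, sc$layers[[i]]$alpha,
                   tolerance = 1e-6, info = ext)
      expect_equal(back$layers[[i]]$color, sc$layers[[i]]$color,
                   tolerance = 1 / 255, info = ext)
    }
  }
})

test_that("export -> import -> export reaches a byte-stable fixed point", {
  sc <- demo_scene()
  f1 <- withr::local_tempfile(fileext = ".glb")
  f2 <- withr::local_tempfile(fileext = ".glb")
  f3 <- withr::local_tempfile(fileext = ".glb")
  export_scene(sc, f1)
  export_scene(read_scene(f1), f2)
  export_scene(read_scene(f2), f3)
  expect_identical(readBin(f2, "raw", file.info(f2)$size),
                   readBin(f3, "raw", file.info(f3)$size))
})

test_that("metrics handle the no-scar case with an undefined fraction", {
  mdl <- test_model()
  seg <- mdl$segmentation
  seg$scar_mask$data[] <- FALSE
  expect_warning(m <- compute_metrics(seg, mdl$layers, NULL), "undefined")
  expect_equal(m$scar_volume_fraction_of_lv, 0)
  expect_true(is.nan(m$endocardial_scar_fraction_of_total))
})

test_that("a full-shell scar yields 100% volume and surface involvement", {
  ph <- fixture("phantom_full", generate_phantom(
    test_spec(scar = list(scar_blob(extent_deg = 360, transmurality = 1))),
    truth_resolution_mm = 0.8))
  mdl <- fixture("model_full",
                 suppressWarnings(scar_pipeline(ph$volume, ph$contours)))
  m <- mdl$metrics
  expect_equal(m$scar_volume_fraction_of_lv, 100)
  expect_equal(m$endocardial_surface_scar_area_fraction, 100)
  expect_equal(m$endocardial_scar_fraction_of_total,
               100 * ph$true_endocardial_scar_fraction, tolerance = 2)
})

test_that("metrics recover the phantom ground truth at 1 mm", {
  ph <- test_phantom()
  m <- test_model()$metrics
  expect_equal(m$scar_volume_fraction_of_lv,
               100 * ph$true_scar_volume_fraction, tolerance = 2)
  expect_equal(m$endocardial_scar_fraction_of_total,
               100 * ph$true_endocardial_scar_fraction, tolerance = 2)
  expect_equal(m$endocardial_surface_scar_area_fraction,
               100 * ph$true_surface_scar_area_fraction, tolerance = 2)
})

test_that("metrics are invariant under a rigid world transform", {
  mdl <- test_model()
  seg <- mdl$segmentation
  R <- rotation_matrix(c(1, 2, 3), 0.7)
  T4 <- diag(4); T4[1:3, 1:3] <- R; T4[1:3, 4] <- c(15, -8, 4)
  rotate_mask <- function(mask) {
    g <- mask$grid
    g$affine <- T4 %*% g$affine
    binary_mask(mask$data, g)
  }
  seg_r <- seg
  seg_r$myocardium_mask <- rotate_mask(seg$myocardium_mask)
  seg_r$scar_mask <- rotate_mask(seg$scar_mask)
  endo_r <- transform_mesh(mdl$endo_mesh, T4)
  epi_r <- transform_mesh(mdl$epi_mesh, T4)
  depth_r <- transmural_depth_field(seg_r$myocardium_mask, endo_r, epi_r)
  layers_r <- layer_labels(depth_r)
  map_r <- project_scar(endo_r, seg_r$scar_mask, layers_r,
                        mode = mdl$surface_map$mode)
  m0 <- mdl$metrics
  m1 <- compute_metrics(seg_r, layers_r, map_r)
  expect_equal(m1$scar_volume_fraction_of_lv, m0$scar_volume_fraction_of_lv)
  expect_equal(m1$endocardial_scar_fraction_of_total,
               m0$endocardial_scar_fraction_of_total, tolerance = 0.2)
  expect_equal(m1$endocardial_surface_scar_area_fraction,
               m0$endocardial_surface_scar_area_fraction, tolerance = 0.2)
})
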