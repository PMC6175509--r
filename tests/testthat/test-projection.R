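test_that("no subendocardial scar gives an all-negative map", {
  mdl <- test_model()
  empty <- binary_mask(array(FALSE, dim(mdl$segmentation$scar_mask$data)),
                       mdl$segmentation$scar_mask$grid)
  for (mode in c("binary", "graded")) {
    map <- project_scar(mdl$endo_mesh, empty, mdl$layers, mode = mode)
    expect_true(all(map$vertex_scar == 0))
    expect_equal(map$scar_area_fraction, 0)
  }
})

test_that("a full-shell scar saturates the surface map in both modes", {
  ph <- fixture("phantom_full", generate_phantom(
    test_spec(scar = list(scar_blob(extent_deg = 360, transmurality = 1))),
    truth_resolution_mm = 0.8))
  mdl <- fixture("model_full",
                 suppressWarnings(scar_pipeline(ph$volume, ph$contours)))
  for (mode in c("binary", "graded")) {
    map <- project_scar(mdl$endo_mesh, mdl$segmentation$scar_mask,
                        mdl$layers, mode = mode)
    expect_true(all(map$vertex_scar == 1))
    expect_equal(map$scar_area_fraction, 1)
  }
  # graded map thresholded at 0.5 equals the binary map here
  g <- project_scar(mdl$endo_mesh, mdl$segmentation$scar_mask, mdl$layers,
                    mode = "graded")
  b <- project_scar(mdl$endo_mesh, mdl$segmentation$scar_mask, mdl$layers,
                    mode = "binary")
  expect_identical(as.numeric(g$vertex_scar >= 0.5), b$vertex_scar)
})

test_that("the graded fraction matches the analytic sector area share", {
  ph <- test_phantom()
  mdl <- test_model()
  expect_equal(mdl$surface_map$scar_area_fraction,
               ph$true_surface_scar_area_fraction, tolerance = 0.03)
})

test_that("scar beyond the subendocardial layer never touches the map", {
  mdl <- test_model()
  seg <- mdl$segmentation
  # deleting all scar voxels with depth >= 1/3 leaves the map bit-identical
  kept <- seg$scar_mask$data & unclass(mdl$layers) == 1L
  pruned <- binary_mask(kept, seg$scar_mask$grid)
  for (mode in c("binary", "graded")) {
    full_map <- project_scar(mdl$endo_mesh, seg$scar_mask, mdl$layers,
                             mode = mode)
    pruned_map <- project_scar(mdl$endo_mesh, pruned, mdl$layers, mode = mode)
    expect_identical(pruned_map$vertex_scar, full_map$vertex_scar)
  }
  # a purely mid/subepicardial blob projects nothing
  ph2 <- fixture("phantom_midepi", generate_phantom(
    test_spec(scar = list(scar_blob(depth_range = c(0.5, 1),
                                    transmurality = 0.5))),
    truth_resolution_mm = 0.8))
  mdl2 <- fixture("model_midepi", scar_pipeline(ph2$volume, ph2$contours))
  expect_equal(mdl2$surface_map$scar_area_fraction, 0)
  expect_equal(ph2$true_surface_scar_area_fraction, 0)
})

test_that("radius validation and defaults behave as documented", {
  mdl <- test_model()
  expect_error(project_scar(mdl$endo_mesh, mdl$segmentation$scar_mask,
                            mdl$layers, radius = 0), "positive")
  map <- project_scar(mdl$endo_mesh, mdl$segmentation$scar_mask, mdl$layers)
  expect_equal(map$radius, 2 * max(mdl$segmentation$scar_mask$grid$spacing))
})

test_that("growing the scar sector never shrinks the surface fraction", {
  fracs <- vapply(c(40, 80, 140), function(ext) {
    ph <- generate_phantom(
      test_spec(scar = list(scar_blob(extent_deg = ext, transmurality = 0.6))),
      truth_resolution_mm = 0.8)
    mdl <- scar_pipeline(ph$volume, ph$contours)
    mdl$surface_map$scar_area_fraction
  }, 0)
  expect_true(all(diff(fracs) > 0))
})

test_that("vertex colours encode the map with linear interpolation", {
  mdl <- test_model()
  map <- mdl$surface_map
  zero_map <- map; zero_map$vertex_scar <- rep(0, length(map$vertex_scar))
  m0 <- vertex_colors_from_map(zero_map, remote_color = c(0.6, 0.3, 0.2))
  expect_true(all(apply(m0$vertex_colors[, 1:3], 1,
                        function(x) all(x == c(0.6, 0.3, 0.2)))))
  bin_map <- map; bin_map$vertex_scar <- rep(c(0, 1), length.out =
                                               length(map$vertex_scar))
  mb <- vertex_colors_from_map(bin_map)
  expect_equal(nrow(unique(mb$vertex_colors)), 2L)
  half <- map; half$vertex_scar <- rep(0.5, length(map$vertex_scar))
  mh <- vertex_colors_from_map(half, scar_color = c(1, 0, 0),
                               remote_color = c(0, 0, 1))
  expect_equal(unique(mh$vertex_colors[, 1]), 0.5)
  expect_equal(unique(mh$vertex_colors[, 3]), 0.5)
})

test_that("texture baking produces a fold-free UV atlas that resamples", {
  mdl <- test_model()
  map <- mdl$surface_map
  baked <- bake_texture(map, resolution = 256)
  uv <- baked$uv
  expect_true(all(uv >= 0 & uv <= 1))
  # all UV triangles share one orientation and have positive area
  f <- map$mesh$faces
  a <- uv[f[, 1], ]; b <- uv[f[, 2], ]; c <- uv[f[, 3], ]
  area2 <- (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) -
           (c[, 1] - a[, 1]) * (b[, 2] - a[, 2])
  expect_true(all(area2 > 0) || all(area2 < 0))
  expect_gt(min(abs(area2)) / 2, 0)
  # resampling the texture at the vertex UVs reproduces the vertex colours
  res <- dim(baked$texture)[1]
  px <- round(uv * (res - 1)) + 1
  t <- pmin(pmax(map$vertex_scar, 0), 1)
  vcol <- outer(t, c(1, 0.9, 0.2)) + outer(1 - t, c(0.65, 0.3, 0.25))
  err <- vapply(seq_len(nrow(uv)), function(v)
    max(abs(baked$texture[px[v, 1], px[v, 2], ] - vcol[v, ])), 0)
  expect_lt(stats::quantile(err, 0.95), 0.1)
  expect_lt(stats::median(err), 1 / 255 + 0.02)
})

test_that("a uniform map bakes to a uniform texture", {
  mdl <- test_model()
  map <- mdl$surface_map
  map$vertex_scar <- rep(0, length(map$vertex_scar))
  baked <- bake_texture(map, resolution = 64,
                        remote_color = c(0.3, 0.4, 0.5))
  expect_equal(range(baked$texture[, , 1]), c(0.3, 0.3))
  expect_equal(range(baked$texture[, , 2]), c(0.4, 0.4))
  expect_equal(range(baked$texture[, , 3]), c(0.5, 0.5))
  png_path <- withr::local_tempfile(fileext = ".png")
  write_texture_png(baked, png_path)
  expect_true(file.exists(png_path))
})

test_that("non-manifold meshes are rejected by the parametrisation", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, -1, 0))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))  # 3 faces share an edge
  map <- structure(list(mesh = trimesh(v, f), vertex_scar = rep(0, 5),
                        scar_area_fraction = 0, mode = "binary", radius = 1),
                   class = "surface_scar_map")
  expect_error(bake_texture(map), "non-manifold")
})
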