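mask_from_array <- function(arr, spacing = c(1, 1, 1)) {
  grid <- lge_volume(array(0, dim(arr)), spacing = spacing,
                     affine = scarmesh:::make_affine(spacing))
  binary_mask(arr, grid)
}

single_voxel_mask <- function() {
  arr <- array(FALSE, c(3, 3, 3)); arr[2, 2, 2] <- TRUE
  mask_from_array(arr)
}

test_that("each voxel becomes a raw cube of 8 vertices and 12 triangles", {
  cm <- voxels_to_cubemesh(single_voxel_mask())
  expect_equal(nrow(cm$mesh$vertices), 8L)
  expect_equal(nrow(cm$mesh$faces), 12L)
  expect_equal(cm$source_voxel_count, 1L)

  arr <- array(FALSE, c(5, 3, 3)); arr[c(1, 5), 2, 2] <- TRUE
  cm2 <- voxels_to_cubemesh(mask_from_array(arr))
  expect_equal(nrow(cm2$mesh$vertices), 16L)
  expect_equal(nrow(cm2$mesh$faces), 24L)
  dd <- deduplicate(cm2)
  expect_equal(max(mesh_components(dd)), 2L)

  set.seed(21)
  arr3 <- array(runif(6 * 6 * 6) > 0.5, c(6, 6, 6))
  cm3 <- voxels_to_cubemesh(mask_from_array(arr3))
  n <- sum(arr3)
  expect_equal(nrow(cm3$mesh$vertices), 8L * n)
  expect_equal(nrow(cm3$mesh$faces), 12L * n)
})

test_that("an empty mask is rejected with an explanatory error", {
  arr <- array(FALSE, c(2, 2, 2))
  expect_error(voxels_to_cubemesh(mask_from_array(arr)), "empty")
})

test_that("dedup yields the documented counts for canonical voxel blocks", {
  # two face-adjacent unit voxels -> 1x1x2 box shell
  arr <- array(FALSE, c(3, 3, 4)); arr[2, 2, 2:3] <- TRUE
  dd <- deduplicate(voxels_to_cubemesh(mask_from_array(arr)))
  expect_equal(nrow(dd$vertices), 12L)
  expect_equal(nrow(dd$faces), 20L)
  expect_true(is_watertight(dd))

  # 2x2x2 block: 27 lattice points minus the interior one; 24 squares
  arr2 <- array(FALSE, c(4, 4, 4)); arr2[2:3, 2:3, 2:3] <- TRUE
  dd2 <- deduplicate(voxels_to_cubemesh(mask_from_array(arr2)))
  expect_equal(nrow(dd2$vertices), 26L)
  expect_equal(nrow(dd2$faces), 48L)
  expect_true(is_watertight(dd2))
  expect_equal(signif(mesh_statistics(dd2)$volume_mm3, 10), 8)
})

test_that("dedup counts equal the brute-force boundary enumeration", {
  set.seed(22)
  for (i in 1:8) {
    d <- sample(3:7, 3, replace = TRUE)
    arr <- array(runif(prod(d)) < runif(1, 0.2, 0.7), d)
    if (!any(arr)) next
    dd <- deduplicate(voxels_to_cubemesh(mask_from_array(arr)))
    bf <- bf_boundary_counts(arr)
    expect_equal(nrow(dd$faces), bf$triangles)
    expect_equal(nrow(dd$vertices), bf$vertices)
  }
})

test_that("deduplication is idempotent", {
  set.seed(23)
  arr <- array(runif(125) > 0.5, c(5, 5, 5))
  dd <- deduplicate(voxels_to_cubemesh(mask_from_array(arr)))
  dd2 <- deduplicate(dd)
  expect_identical(dd2$vertices, dd$vertices)
  expect_identical(dd2$faces, dd$faces)
})

test_that("keep_one retains interior walls instead of removing them", {
  arr <- array(FALSE, c(3, 3, 4)); arr[2, 2, 2:3] <- TRUE
  kept <- deduplicate(voxels_to_cubemesh(mask_from_array(arr)),
                      keep_one = TRUE)
  expect_equal(nrow(kept$faces), 22L)  # 10 boundary squares + shared wall
})

test_that("mesh statistics of the unit cube are exact", {
  st <- mesh_statistics(cube_mesh())
  expect_equal(st$vertices, 8L)
  expect_equal(st$faces, 12L)
  expect_equal(st$volume_mm3, 1)
  expect_equal(st$components, 1L)
  expect_true(st$watertight)
})

test_that("enclosed volume equals voxel count times voxel volume exactly", {
  set.seed(24)
  for (i in 1:10) {
    d <- sample(3:9, 3, replace = TRUE)
    spacing <- round(runif(3, 0.2, 2.5), 3)
    arr <- array(runif(prod(d)) < 0.45, d)
    if (!any(arr)) next
    dd <- deduplicate(voxels_to_cubemesh(mask_from_array(arr, spacing)))
    st <- suppressWarnings(mesh_statistics(dd))
    expect_identical(st$volume_mm3, sum(arr) * prod(spacing))
  }
})

test_that("face count is twice the exposed-face count from a 6-neighbour scan", {
  set.seed(25)
  for (i in 1:6) {
    d <- sample(3:8, 3, replace = TRUE)
    arr <- array(runif(prod(d)) < 0.5, d)
    if (!any(arr)) next
    dd <- deduplicate(voxels_to_cubemesh(mask_from_array(arr)))
    expect_equal(nrow(dd$faces), 2L * bf_exposed_faces(arr))
  }
})

test_that("every component is closed and encloses positive volume", {
  set.seed(26)
  for (i in 1:5) {
    d <- sample(4:7, 3, replace = TRUE)
    arr <- array(runif(prod(d)) < 0.4, d)
    if (!any(arr)) next
    dd <- deduplicate(voxels_to_cubemesh(mask_from_array(arr)))
    comp <- mesh_components(dd)
    for (id in unique(comp)) {
      sub <- mesh_component(dd, id)
      expect_true(is_closed(sub))
      expect_gt(scarmesh:::signed_volume(sub), 0)
    }
  }
})

test_that("the phantom scar mesh conserves scar volume exactly", {
  mdl <- test_model()
  st <- mesh_statistics(mdl$scar_mesh)
  n <- sum(mdl$segmentation$scar_mask$data)
  expect_identical(st$volume_mm3,
                   n * prod(mdl$segmentation$scar_mask$grid$spacing))
  expect_true(is_closed(mdl$scar_mesh))
})
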