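square_poly <- function(lo, hi) cbind(c(lo, hi, hi, lo), c(lo, lo, hi, hi))

# 12x12x3 grid, 1 mm voxels with centres at half-integer mm
annulus_grid <- function() {
  aff <- diag(4); aff[1:3, 4] <- c(0.5, 0.5, 0.5)
  lge_volume(array(0, c(12, 12, 3)), spacing = c(1, 1, 1), affine = aff)
}

test_that("square-annulus rasterisation matches the brute-force count", {
  grid <- annulus_grid()
  cs <- contour_set(list(
    list(surface = "lv_epi", slice = 1, points = square_poly(0, 10)),
    list(surface = "lv_endo", slice = 1, points = square_poly(3, 7))))
  mask <- myocardium_mask_from_contours(cs, grid)
  expect_equal(sum(mask$data[, , 2]), 100 - 16)
  expect_equal(sum(mask$data), 84)  # only the contoured slice
  # brute-force point-in-polygon oracle over all centres
  for (i in 0:11) for (j in 0:11) {
    cx <- 0.5 + i; cy <- 0.5 + j
    want <- bf_point_in_polygon(cx, cy, square_poly(0, 10)) &&
            !bf_point_in_polygon(cx, cy, square_poly(3, 7))
    expect_identical(mask$data[i + 1, j + 1, 2], want)
  }
})

test_that("coincident endo and epi contours give an empty mask", {
  grid <- annulus_grid()
  cs <- contour_set(list(
    list(surface = "lv_epi", slice = 0, points = square_poly(2, 8)),
    list(surface = "lv_endo", slice = 0, points = square_poly(2, 8))))
  expect_false(any(myocardium_mask_from_contours(cs, grid)$data))
})

test_that("an endo contour escaping the epi contour warns but proceeds", {
  grid <- annulus_grid()
  cs <- contour_set(list(
    list(surface = "lv_epi", slice = 0, points = square_poly(1, 6)),
    list(surface = "lv_endo", slice = 0, points = square_poly(4, 9))))
  expect_warning(m <- myocardium_mask_from_contours(cs, grid), "contained")
  expect_gt(sum(m$data), 0)
})

test_that("rasterised phantom contours recover the truth myocardium", {
  ph <- test_phantom()
  mask <- myocardium_mask_from_contours(ph$contours, ph$volume)
  truth <- ph$myocardium_mask$data
  dice <- 2 * sum(mask$data & truth) / (sum(mask$data) + sum(truth))
  expect_gt(dice, 0.95)
})

test_that("FWHM threshold is half the reference maximum", {
  grid <- lge_volume(array(c(10, 10, 10, 10, 100), c(5, 1, 1)))
  myo <- binary_mask(array(TRUE, c(5, 1, 1)), grid)
  seg <- fwhm_scar_mask(grid, myo)
  expect_equal(seg$reference_max, 100)
  expect_equal(seg$threshold, 50)
  expect_equal(sum(seg$scar_mask$data), 1L)
  expect_identical(which(seg$scar_mask$data), 5L)
})

test_that("uniform intensities are flagged as degenerate contrast", {
  grid <- lge_volume(array(5, c(3, 1, 1)))
  myo <- binary_mask(array(TRUE, c(3, 1, 1)), grid)
  expect_warning(seg <- fwhm_scar_mask(grid, myo), "degenerate")
  expect_equal(seg$threshold, 2.5)
  expect_true(all(seg$scar_mask$data))
  expect_error(fwhm_scar_mask(grid, binary_mask(array(FALSE, c(3, 1, 1)),
                                                grid)),
               "empty")
})

test_that("vectorised FWHM equals the per-voxel brute-force loop", {
  set.seed(5)
  for (i in 1:5) {
    d <- c(6, 5, 4)
    vol <- lge_volume(array(rnorm(prod(d), 40, 15), d))
    myo <- binary_mask(array(runif(prod(d)) > 0.4, d), vol)
    if (!any(myo$data)) next
    seg <- fwhm_scar_mask(vol, myo)
    bf <- bf_fwhm_scar(vol$data, myo$data)
    expect_identical(seg$scar_mask$data, bf$scar)
    expect_equal(seg$threshold, bf$threshold)
  }
})

test_that("FWHM segmentation is invariant under positive intensity scaling", {
  set.seed(6)
  d <- c(7, 6, 5)
  vol <- lge_volume(array(rgamma(prod(d), 3, 0.1), d))
  myo <- binary_mask(array(runif(prod(d)) > 0.3, d), vol)
  seg <- fwhm_scar_mask(vol, myo)
  for (a in c(0.02, 3.7, 1e4)) {
    sv <- vol; sv$data <- a * vol$data
    seg2 <- fwhm_scar_mask(sv, myo)
    expect_identical(seg2$scar_mask$data, seg$scar_mask$data)
    expect_equal(seg2$threshold, a * seg$threshold)
  }
})

test_that("FWHM supports a reference region and a robust percentile", {
  d <- c(10, 1, 1)
  vol <- lge_volume(array(c(rep(10, 8), 80, 1000), d))
  myo <- binary_mask(array(TRUE, d), vol)
  ref <- binary_mask(array(c(rep(FALSE, 8), TRUE, FALSE), d), vol)
  expect_equal(fwhm_scar_mask(vol, myo, reference_region = ref)$threshold, 40)
  # a low percentile drops the threshold below every intensity here, which
  # legitimately trips the degenerate-contrast warning
  expect_warning(seg <- fwhm_scar_mask(vol, myo, percentile = 0.5),
                 "degenerate")
  expect_lt(seg$threshold, 40)
})

concentric_shell <- function(a = 20, b = 30, spacing = 1) {
  n <- 2L * ceiling((b + 2) / spacing) + 1L
  aff <- diag(c(rep(spacing, 3), 1)); aff[1:3, 4] <- -(n - 1) / 2 * spacing
  grid <- lge_volume(array(0, c(n, n, n)), spacing = rep(spacing, 3),
                     affine = aff)
  p <- voxel_centers(grid)
  r <- sqrt(rowSums(p^2))
  mask <- binary_mask(array(r >= a & r <= b, dim(grid$data)), grid)
  list(grid = grid, mask = mask, r = array(r, dim(grid$data)))
}

test_that("transmural depth matches (r - a)/(b - a) on concentric spheres", {
  shell <- fixture("shell20_30", concentric_shell())
  endo <- icosphere(20, subdivisions = 4)
  epi <- icosphere(30, subdivisions = 4)
  depth <- transmural_depth_field(shell$mask, endo, epi)
  inside <- shell$mask$data
  expected <- (shell$r[inside] - 20) / 10
  err <- depth[inside] - expected
  expect_lt(sqrt(mean(err^2)), 0.02)
  expect_true(all(depth[inside] >= 0 & depth[inside] <= 1))
  expect_true(all(is.nan(depth[!inside])))
  # a voxel at radius 25 sits mid-wall
  mid <- inside & abs(shell$r - 25) < 0.2
  expect_equal(mean(depth[mid]), 0.5, tolerance = 0.02)
})

test_that("voxel centres on a surface get boundary depth values", {
  endo <- icosphere(20, subdivisions = 3)
  epi <- icosphere(30, subdivisions = 3)
  on_endo <- endo$vertices[1, ]
  aff <- diag(4); aff[1:3, 4] <- on_endo
  grid <- lge_volume(array(0, c(1, 1, 1)), affine = aff)
  mask <- binary_mask(array(TRUE, c(1, 1, 1)), grid)
  expect_equal(as.vector(transmural_depth_field(mask, endo, epi)), 0)
  aff[1:3, 4] <- epi$vertices[1, ]
  grid2 <- lge_volume(array(0, c(1, 1, 1)), affine = aff)
  mask2 <- binary_mask(array(TRUE, c(1, 1, 1)), grid2)
  expect_equal(as.vector(transmural_depth_field(mask2, endo, epi)), 1)
})

test_that("layer labels follow the half-open third conventions", {
  depth <- array(c(0, 0.2, 1 / 3, 0.5, 2 / 3, 0.9, 1, NaN), c(8, 1, 1))
  lab <- layer_labels(depth)
  expect_equal(as.vector(unclass(lab)), c(1, 1, 2, 2, 3, 3, 3, 0))
})

test_that("layers partition the myocardium with analytic shell shares", {
  shell <- fixture("shell20_30", concentric_shell())
  endo <- icosphere(20, subdivisions = 4)
  epi <- icosphere(30, subdivisions = 4)
  depth <- transmural_depth_field(shell$mask, endo, epi)
  lab <- unclass(layer_labels(depth))
  n_myo <- sum(shell$mask$data)
  expect_equal(sum(lab != 0), n_myo)  # partition: every myocardial voxel
  r1 <- 20 + 10 / 3; r2 <- 20 + 20 / 3
  shares <- c((r1^3 - 20^3), (r2^3 - r1^3), (30^3 - r2^3)) / (30^3 - 20^3)
  got <- c(sum(lab == 1), sum(lab == 2), sum(lab == 3)) / n_myo
  expect_lt(max(abs(got - shares)), 0.03)
})

test_that("depth is monotone along radial rays through the shell", {
  endo <- icosphere(20, subdivisions = 4)
  epi <- icosphere(30, subdivisions = 4)
  dir <- c(1, 2, 0.5) / sqrt(sum(c(1, 2, 0.5)^2))
  radii <- seq(20.5, 29.5, by = 0.5)
  pts <- outer(radii, dir)
  de <- point_mesh_distance(pts, endo)
  dp <- point_mesh_distance(pts, epi)
  depth <- de / (de + dp)
  expect_true(all(diff(depth) > 0))
})
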