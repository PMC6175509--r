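test_that("contour point clouds carry every polygon point into world mm", {
  ph <- test_phantom()
  recs <- Filter(function(r) r$surface == "lv_endo", ph$contours$records)
  pts <- contours_to_pointcloud(ph$contours, "lv_endo", ph$volume)
  expect_equal(nrow(pts), sum(vapply(recs, function(r) nrow(r$points), 0L)))
  # every point lies exactly on the endo ellipsoid
  sp <- ph$spec
  m <- sqrt((pts[, 1] / sp$lv_endo_radii[1])^2 +
            (pts[, 2] / sp$lv_endo_radii[2])^2 +
            (pts[, 3] / sp$lv_endo_radii[3])^2)
  expect_lt(max(abs(m - 1)), 1e-9)
})

test_that("a label on fewer than 2 slices or absent is an error", {
  cs <- contour_set(list(list(surface = "rv_endo", slice = 0,
                              points = cbind(c(0, 1, 0), c(0, 0, 1)),
                              z = 0)))
  expect_error(contours_to_pointcloud(cs, "rv_endo"), "fewer than 2")
  expect_error(contours_to_pointcloud(cs, "lv_endo"), "no contours")
})

test_that("clustering decimation collapses each occupied cell to a centroid", {
  set.seed(3)
  inside <- matrix(runif(300, 0, 0.9), ncol = 3)  # 100 points, one cell
  out <- clustering_decimation(inside, cell_size = 1)
  expect_equal(nrow(out), 1L)
  expect_equal(out[1, ], colMeans(inside))

  lattice <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3)) * 2
  expect_equal(nrow(clustering_decimation(lattice, cell_size = 1.5)),
               nrow(lattice))

  cloud <- matrix(rnorm(900, 0, 5), ncol = 3)
  got <- clustering_decimation(cloud, cell_size = 1.2)
  oracle <- bf_decimate(cloud, 1.2)
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ],
               tolerance = 1e-12)
})

test_that("normals of a coplanar cloud are consistent +/- z", {
  set.seed(4)
  pts <- cbind(matrix(runif(200, -5, 5), ncol = 2), 0)
  cl <- estimate_normals(pts, k = 10)
  expect_lt(max(abs(abs(cl$normals[, 3]) - 1)), 1e-6)
  expect_true(all(cl$normals[, 3] > 0) || all(cl$normals[, 3] < 0))
})

test_that("sphere-cloud normals point radially outward within 5 degrees", {
  pts <- fibonacci_sphere(2000, radius = 20)
  cl <- estimate_normals(pts, k = 10)
  radial <- pts / 20
  cosang <- rowSums(cl$normals * radial)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  expect_gte(mean(ang < 5), 0.99)
  expect_gte(mean(cosang > 0), 0.99)  # outward, not inward
})

test_that("normal estimation needs more points than neighbours", {
  pts <- fibonacci_sphere(12, radius = 5)
  expect_error(estimate_normals(pts, k = 12), "more points")
})

test_that("reconstruction from a sphere cloud is accurate and watertight", {
  cl <- fixture("sphere_cloud", estimate_normals(fibonacci_sphere(2000, 20), 10))
  mesh <- fixture("sphere_mesh", reconstruct_surface(cl, depth = 7))
  expect_true(is_watertight(mesh))
  expect_equal(euler_characteristic(mesh), 2L)
  r_mesh <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(r_mesh - 20)), 1.0)
  ref <- fibonacci_sphere(5000, 20)
  expect_lt(max(point_mesh_distance(ref, mesh)), 1.0)
  # deterministic for fixed input
  again <- reconstruct_surface(cl, depth = 7)
  expect_identical(again$vertices, mesh$vertices)
  expect_identical(again$faces, mesh$faces)
})

test_that("a degenerate (collinear) cloud is rejected", {
  t <- seq(0, 1, length.out = 50)
  line <- cbind(t, 2 * t, 3 * t)
  nrm <- matrix(rep(c(1, 0, 0), each = 50), ncol = 3)
  expect_error(reconstruct_surface(oriented_pointcloud(line, nrm)),
               "degenerate")
})

test_that("the phantom endo surface is recovered within half a voxel", {
  ph <- test_phantom()
  mesh <- surface_from_contours(ph$contours, "lv_endo", ph$volume)
  plane <- basal_plane(ph$contours, ph$volume)
  mesh <- clip_at_base(mesh, plane)
  sp <- ph$spec
  v <- mesh$vertices
  dir_r <- sqrt(rowSums(v^2))
  m <- sqrt((v[, 1] / sp$lv_endo_radii[1])^2 + (v[, 2] / sp$lv_endo_radii[2])^2 +
            (v[, 3] / sp$lv_endo_radii[3])^2)
  radial_residual <- dir_r * (1 - 1 / m)  # distance along the ray to m = 1
  expect_lt(mean(abs(radial_residual)), 0.5 * max(sp$spacing))
})

test_that("clipping a sphere at the equator keeps half the area", {
  mesh <- icosphere(10, subdivisions = 4)
  plane <- list(point = c(0, 0, 0), normal = c(0, 0, 1))
  clipped <- clip_at_base(mesh, plane)
  expect_equal(mesh_area(clipped) / mesh_area(mesh), 0.5, tolerance = 0.02)
  ctr <- (clipped$vertices[clipped$faces[, 1], ] +
          clipped$vertices[clipped$faces[, 2], ] +
          clipped$vertices[clipped$faces[, 3], ]) / 3
  expect_true(all(ctr[, 3] <= 0))
})

test_that("a plane missing the mesh leaves it unchanged with a warning", {
  mesh <- icosphere(5, subdivisions = 2)
  plane <- list(point = c(0, 0, 100), normal = c(0, 0, 1))
  expect_warning(out <- clip_at_base(mesh, plane), "does not intersect")
  expect_identical(out$vertices, mesh$vertices)
  expect_identical(out$faces, mesh$faces)
})

test_that("the full chain reproduces both phantom surfaces within a voxel", {
  ph <- test_phantom()
  sp <- ph$spec
  plane <- basal_plane(ph$contours, ph$volume)
  for (surf in c("lv_endo", "lv_epi")) {
    radii <- if (surf == "lv_endo") sp$lv_endo_radii else sp$lv_epi_radii
    mesh <- clip_at_base(surface_from_contours(ph$contours, surf, ph$volume),
                         plane)
    d <- scarmesh:::ellipsoid_surface_distance(mesh$vertices, radii)
    expect_lt(stats::quantile(d, 0.99), max(sp$spacing))
  }
})
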