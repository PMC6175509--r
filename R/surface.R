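#' Merge contours of one surface into a 3D point cloud
#'
#' Every contour point of the requested surface is lifted to world
#' coordinates using its slice position; the output point count is the sum
#' of the polygon sizes.
#'
#' @param contours a [contour_set()].
#' @param surface_label one of `lv_endo`, `lv_epi`, `rv_endo`, `rv_epi`.
#' @param grid optional [lge_volume()] supplying slice z positions when the
#'   contour records do not carry them.
#' @return n x 3 matrix of points in mm.
#' @export
contours_to_pointcloud <- function(contours, surface_label, grid = NULL) {
  recs <- surface_records(contours, surface_label, grid)
  slices <- unique(vapply(recs, function(r) r$slice, 0L))
  if (length(slices) < 2L)
    stop("surface '", surface_label, "' is present on fewer than 2 slices")
  do.call(rbind, lapply(recs, function(r)
    cbind(r$points, rep(r$z, nrow(r$points)))))
}

#' Clustering decimation of a point cloud
#'
#' Organises the points on a uniform 3D grid of the given cell size and
#' replaces the points of each occupied cell by their centroid, so the
#' output count equals the number of occupied cells.
#'
#' @param points n x 3 matrix (mm).
#' @param cell_size grid cell edge length in mm (> 0).
#' @return m x 3 matrix of cell centroids, in first-occurrence cell order.
#' @export
clustering_decimation <- function(points, cell_size) {
  stopifnot(cell_size > 0)
  points <- matrix(as.numeric(points), ncol = 3)
  cellidx <- floor(sweep(points, 2, apply(points, 2, min)) / cell_size)
  key <- paste(cellidx[, 1], cellidx[, 2], cellidx[, 3])
  grp <- match(key, unique(key))
  out <- rowsum(points, grp, reorder = TRUE) / as.vector(table(grp))
  dimnames(out) <- NULL
  out
}

#' Oriented point cloud
#'
#' @param points n x 3 matrix (mm).
#' @param normals n x 3 matrix of unit vectors.
#' @return An object of class `oriented_pointcloud`.
#' @export
oriented_pointcloud <- function(points, normals) {
  points <- matrix(as.numeric(points), ncol = 3)
  normals <- matrix(as.numeric(normals), ncol = 3)
  if (nrow(points) < 4L) stop("an oriented cloud needs at least 4 points")
  if (nrow(points) != nrow(normals)) stop("points/normals length mismatch")
  nn <- sqrt(rowSums(normals^2))
  if (any(abs(nn - 1) > 1e-6)) stop("normals must be unit length")
  structure(list(points = points, normals = normals),
            class = "oriented_pointcloud")
}

#' @export
print.oriented_pointcloud <- function(x, ...) {
  cat("<oriented_pointcloud> ", nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Estimate consistently oriented surface normals
#'
#' The normal at each point is the smallest-eigenvalue eigenvector of the
#' covariance of its k nearest neighbours.  Signs are first propagated along
#' a breadth-first traversal of the k-NN graph for local consistency, then
#' globally flipped so that normals point outward (positive mean dot product
#' with the direction from the cloud centroid).
#'
#' @param points n x 3 matrix (mm), n > k.
#' @param k neighbour count (default 10).
#' @return An [oriented_pointcloud()].
#' @export
estimate_normals <- function(points, k = 10) {
  points <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(points)
  if (n <= k) stop("need more points (", n, ") than neighbours k = ", k)
  nb <- cpp_knn(points, points, as.integer(k + 1))$index  # includes self
  normals <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    nbr <- points[nb[i, ], , drop = FALSE]
    cv <- crossprod(sweep(nbr, 2, colMeans(nbr)))
    normals[i, ] <- eigen(cv, symmetric = TRUE)$vectors[, 3]
  }
  # breadth-first sign propagation over the k-NN graph
  visited <- logical(n)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (j in nb[i, -1L]) {
      if (!visited[j]) {
        if (sum(normals[i, ] * normals[j, ]) < 0) normals[j, ] <- -normals[j, ]
        visited[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  if (!all(visited)) {  # disconnected graph: orient each leftover by centroid
    ctr <- colMeans(points)
    for (i in which(!visited)) {
      if (sum(normals[i, ] * (points[i, ] - ctr)) < 0)
        normals[i, ] <- -normals[i, ]
    }
  }
  ctr <- colMeans(points)
  outward <- sweep(points, 2, ctr)
  if (sum(rowSums(normals * outward)) < 0) normals <- -normals
  oriented_pointcloud(points, normals)
}

#' Implicit-function surface reconstruction
#'
#' Reconstructs a watertight triangle mesh from an oriented point cloud via
#' an implicit function: the signed distance at any location is the
#' inverse-distance-weighted mean of the tangent-plane distances of the k
#' nearest oriented points, intersected with the cloud's bounding box
#' expanded by `cap_margin` (which closes surfaces whose clouds are open,
#' e.g. at the ventricular base).  The zero level set is extracted by
#' marching tetrahedra on a regular grid with `2^depth` cells along the
#' longest bounding-box axis.
#'
#' @param cloud an [oriented_pointcloud()].
#' @param depth grid resolution exponent (default 7, i.e. 128 cells).
#' @param k neighbours used for the signed-distance estimate (default 8).
#' @param cap_margin bounding-box expansion in multiples of the grid step
#'   (default 3).
#' @return A watertight [trimesh()].
#' @export
reconstruct_surface <- function(cloud, depth = 7, k = 8, cap_margin = 3) {
  stopifnot(inherits(cloud, "oriented_pointcloud"))
  P <- cloud$points
  rng <- apply(P, 2, range)
  extent <- rng[2, ] - rng[1, ]
  if (min(extent) <= 0 || qr(sweep(P, 2, colMeans(P)))$rank < 3)
    stop("degenerate point cloud: points are collinear or coplanar")
  h <- max(extent) / 2^depth
  pad <- (cap_margin + 3) * h
  origin <- rng[1, ] - pad
  top <- rng[2, ] + pad
  dims <- ceiling((top - origin) / h) + 1L
  gx <- origin[1] + h * (0:(dims[1] - 1))
  gy <- origin[2] + h * (0:(dims[2] - 1))
  gz <- origin[3] + h * (0:(dims[3] - 1))
  Q <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  sdf <- cpp_plane_sdf(P, cloud$normals, Q, as.integer(min(k, nrow(P))),
                       band = 3 * h)
  # intersect with the expanded bounding box: signed distance to the box
  lo <- rng[1, ] - cap_margin * h
  hi <- rng[2, ] + cap_margin * h
  qx <- pmax(lo[1] - Q[, 1], Q[, 1] - hi[1])
  qy <- pmax(lo[2] - Q[, 2], Q[, 2] - hi[2])
  qz <- pmax(lo[3] - Q[, 3], Q[, 3] - hi[3])
  outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2)
  inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
  box_sdf <- outside + inside
  field <- pmax(sdf, box_sdf)
  mt <- cpp_marching_tets(field, dims, origin, c(h, h, h))
  if (nrow(mt$vertices) == 0)
    stop("reconstruction produced no surface (degenerate cloud?)")
  trimesh(mt$vertices, mt$faces)
}

#' Clip a mesh at a basal plane
#'
#' Removes faces whose centroid lies on the positive side of the plane
#' (beyond the base); the cut boundary is left open.
#'
#' @param mesh a [trimesh()].
#' @param plane `list(point = c(x, y, z), normal = c(nx, ny, nz))`, the
#'   normal pointing toward the side to remove.
#' @return The clipped [trimesh()] (unchanged, with a warning, if the plane
#'   does not intersect the mesh).
#' @export
clip_at_base <- function(mesh, plane) {
  ctr <- face_centroids(mesh)
  s <- as.vector(sweep(ctr, 2, plane$point) %*% plane$normal)
  if (all(s > 0) || all(s <= 0)) {
    warning("basal plane does not intersect the mesh; returned unchanged")
    return(mesh)
  }
  subset_faces(mesh, s <= 0)
}

#' Basal clipping plane from the most basal contoured slice
#'
#' @param contours a [contour_set()].
#' @param grid optional [lge_volume()] for slice z positions.
#' @param offset_mm shift of the plane beyond the most basal slice
#'   (default 0).
#' @return `list(point, normal)` with the normal pointing past the base.
#' @export
basal_plane <- function(contours, grid = NULL, offset_mm = 0) {
  z <- vapply(contours$records, function(r) {
    if (!is.null(r$z)) r$z else slice_world_z(grid, r$slice)
  }, 0)
  list(point = c(0, 0, max(z) + offset_mm), normal = c(0, 0, 1))
}

#' Reconstruct one anatomical surface from contours
#'
#' Convenience chain: [contours_to_pointcloud()] -> [clustering_decimation()]
#' -> [estimate_normals()] -> [reconstruct_surface()].
#'
#' @param contours a [contour_set()].
#' @param surface_label surface to reconstruct.
#' @param grid optional [lge_volume()] for slice positions.
#' @param cell_size decimation cell in mm; default twice the in-plane
#'   spacing of `grid` (2 mm without a grid).
#' @param k_normals,depth,k_sdf parameters of the downstream stages.
#' @return A watertight [trimesh()].
#' @export
surface_from_contours <- function(contours, surface_label, grid = NULL,
                                  cell_size = NULL, k_normals = 10,
                                  depth = 7, k_sdf = 8) {
  if (is.null(cell_size))
    cell_size <- if (!is.null(grid)) 2 * max(grid$spacing[1:2]) else 2
  pts <- contours_to_pointcloud(contours, surface_label, grid)
  dec <- clustering_decimation(pts, cell_size)
  cloud <- estimate_normals(dec, k = k_normals)
  reconstruct_surface(cloud, depth = depth, k = k_sdf)
}
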