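#' Indexed triangle mesh
#'
#' @param vertices V x 3 numeric matrix of positions in mm.
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param vertex_colors optional V x 4 matrix of RGBA values in \[0, 1\].
#' @param material optional `list(color = RGB in [0,1], alpha, name)`.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, vertex_colors = NULL, material = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
      stop("degenerate faces: each face needs 3 distinct vertices")
  }
  if (!is.null(vertex_colors)) {
    vertex_colors <- matrix(as.numeric(vertex_colors), ncol = 4)
    if (nrow(vertex_colors) != nrow(vertices))
      stop("vertex_colors must have one RGBA row per vertex")
  }
  if (!is.null(material)) {
    material$color <- as.numeric(material$color)
    material$alpha <- if (is.null(material$alpha)) 1 else as.numeric(material$alpha)
    if (material$alpha < 0 || material$alpha > 1) stop("alpha must be in [0, 1]")
    if (is.null(material$name)) material$name <- "material"
  }
  structure(list(vertices = vertices, faces = faces,
                 vertex_colors = vertex_colors, material = material),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat("<trimesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces), " faces",
      if (!is.null(x$vertex_colors)) ", per-vertex colors",
      if (!is.null(x$material)) paste0(", material '", x$material$name,
                                       "' alpha ", x$material$alpha),
      "\n", sep = "")
  invisible(x)
}

#' Is every edge shared by exactly two faces?
#'
#' @param mesh a [trimesh()].
#' @return TRUE for a closed (watertight) mesh.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(cpp_edge_counts(mesh$faces) == 2L)
}

#' Is the mesh closed (no boundary edges)?
#'
#' Weaker than [is_watertight()]: every undirected edge must bound an even
#' number (>= 2) of faces.  Voxel shells whose cubes touch only across a
#' lattice edge are closed but not 2-manifold (4 faces meet at the shared
#' edge).
#'
#' @param mesh a [trimesh()].
#' @return TRUE when no edge is a boundary edge.
#' @export
is_closed <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  cnt <- cpp_edge_counts(mesh$faces)
  all(cnt %% 2L == 0L)
}

#' Euler characteristic V - E + F
#'
#' @param mesh a [trimesh()].
#' @return Integer Euler characteristic (2 for a sphere-topology mesh).
#' @export
euler_characteristic <- function(mesh) {
  used <- unique(as.vector(mesh$faces))
  length(used) - length(cpp_edge_counts(mesh$faces)) + nrow(mesh$faces)
}

face_cross <- function(mesh) {
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  e1 <- v1 - v0; e2 <- v2 - v0
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Total surface area of a mesh
#'
#' @param mesh a [trimesh()].
#' @return Area in mm^2.
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(face_cross(mesh)^2))) / 2

#' Per-face areas
#' @param mesh a [trimesh()].
#' @return Numeric vector of face areas in mm^2.
#' @export
face_areas <- function(mesh) sqrt(rowSums(face_cross(mesh)^2)) / 2

face_centroids <- function(mesh) {
  (mesh$vertices[mesh$faces[, 1], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 2], , drop = FALSE] +
   mesh$vertices[mesh$faces[, 3], , drop = FALSE]) / 3
}

# Signed volume via the divergence theorem; uses exact integer-lattice
# coordinates when the mesh carries them (voxel cube meshes).
signed_volume <- function(mesh) {
  lat <- attr(mesh, "lattice")
  if (!is.null(lat)) {
    v0 <- lat[mesh$faces[, 1], , drop = FALSE]
    v1 <- lat[mesh$faces[, 2], , drop = FALSE]
    v2 <- lat[mesh$faces[, 3], , drop = FALSE]
    s <- sum(v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
             v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
             v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]))
    return((s / 6) * prod(attr(mesh, "lattice_spacing")))
  }
  v0 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  v1 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(v0[, 1] * (v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]) -
      v0[, 2] * (v1[, 1] * v2[, 3] - v1[, 3] * v2[, 1]) +
      v0[, 3] * (v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])) / 6
}

#' Connected components of a mesh
#'
#' @param mesh a [trimesh()].
#' @return Integer vector: a 1-based component id per face.
#' @export
mesh_components <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(integer())
  cpp_face_components(mesh$faces, nrow(mesh$vertices))
}

#' Extract one connected component as a mesh
#'
#' @param mesh a [trimesh()].
#' @param id component id as returned by [mesh_components()].
#' @return A [trimesh()] containing only that component's faces.
#' @export
mesh_component <- function(mesh, id) {
  comp <- mesh_components(mesh)
  subset_faces(mesh, comp == id)
}

subset_faces <- function(mesh, keep) {
  f <- mesh$faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices)); remap[used] <- seq_along(used)
  out <- trimesh(mesh$vertices[used, , drop = FALSE],
                 matrix(remap[f], ncol = 3),
                 vertex_colors = if (!is.null(mesh$vertex_colors))
                   mesh$vertex_colors[used, , drop = FALSE],
                 material = mesh$material)
  lat <- attr(mesh, "lattice")
  if (!is.null(lat)) {
    attr(out, "lattice") <- lat[used, , drop = FALSE]
    attr(out, "lattice_spacing") <- attr(mesh, "lattice_spacing")
  }
  out
}

#' Mesh summary statistics
#'
#' Vertex and face counts, enclosed volume (divergence theorem over oriented
#' faces) and number of connected components.  A non-watertight mesh yields a
#' warning and the absolute value of the signed volume.
#'
#' @param mesh a [trimesh()].
#' @return `list(vertices, faces, volume_mm3, components, watertight)`.
#' @export
mesh_statistics <- function(mesh) {
  wt <- is_watertight(mesh)
  vol <- signed_volume(mesh)
  if (!wt) {
    warning("mesh is not watertight; reporting |signed volume|")
    vol <- abs(vol)
  }
  ncomp <- if (nrow(mesh$faces)) max(mesh_components(mesh)) else 0L
  list(vertices = nrow(mesh$vertices), faces = nrow(mesh$faces),
       volume_mm3 = vol, components = ncomp, watertight = wt)
}

#' Distance from points to a mesh surface
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a [trimesh()].
#' @return Unsigned Euclidean distances in mm.
#' @export
point_mesh_distance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_point_mesh_distance(points, mesh$vertices, mesh$faces)
}

#' Two-sided Hausdorff-type distance between a mesh and a point sample
#'
#' Computes max over mesh vertices and face centroids of the distance to the
#' reference sample, and max over reference points of the distance to the
#' mesh, returning the larger of the two.
#'
#' @param mesh a [trimesh()].
#' @param reference_points n x 3 matrix densely sampling the reference
#'   surface.
#' @return Distance in mm.
#' @export
hausdorff_to_points <- function(mesh, reference_points) {
  reference_points <- matrix(as.numeric(reference_points), ncol = 3)
  qs <- rbind(mesh$vertices, face_centroids(mesh))
  a <- max(cpp_knn(reference_points, qs, 1L)$distance)
  b <- max(point_mesh_distance(reference_points, mesh))
  max(a, b)
}

#' Apply a rigid (or affine) transform to a mesh
#'
#' @param mesh a [trimesh()].
#' @param transform 4x4 homogeneous transform.
#' @return The transformed [trimesh()].
#' @export
transform_mesh <- function(mesh, transform) {
  v <- cbind(mesh$vertices, 1) %*% t(transform)
  trimesh(v[, 1:3, drop = FALSE], mesh$faces,
          vertex_colors = mesh$vertex_colors, material = mesh$material)
}

#' Axis-aligned unit cube mesh
#'
#' @param center length-3 centre (mm).
#' @param size length-3 edge lengths (mm).
#' @return A watertight [trimesh()] with 8 vertices and 12 outward-oriented
#'   triangles.
#' @export
cube_mesh <- function(center = c(0, 0, 0), size = c(1, 1, 1)) {
  size <- rep_len(as.numeric(size), 3)
  corners <- as.matrix(expand.grid(x = c(-.5, .5), y = c(-.5, .5),
                                   z = c(-.5, .5)))
  v <- sweep(sweep(corners, 2, size, "*"), 2, center, "+")
  trimesh(v, cube_face_triangles())
}

# 12 outward-oriented triangles over the expand.grid corner ordering
# (x fastest): corner index = 1 + ix + 2*iy + 4*iz
cube_face_triangles <- function() {
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  rbind(
    quad(1, 5, 7, 3),  # x = -: outward -x
    quad(2, 4, 8, 6),  # x = +
    quad(1, 2, 6, 5),  # y = -
    quad(3, 7, 8, 4),  # y = +
    quad(1, 3, 4, 2),  # z = -
    quad(5, 6, 8, 7))  # z = +
}

#' Subdivided icosahedron sphere mesh
#'
#' @param radius sphere radius (mm).
#' @param center length-3 centre (mm).
#' @param subdivisions number of 4-to-1 subdivisions (default 3).
#' @return A watertight [trimesh()] with vertices exactly on the sphere.
#' @export
icosphere <- function(radius = 1, center = c(0, 0, 0), subdivisions = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, "+")
  trimesh(v, f)
}
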