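#' Render scar voxels as cubes at native resolution
#'
#' Every true voxel contributes an axis-aligned cuboid of size (dx, dy, dz)
#' centred at the voxel's world centre, each cuboid face split into two
#' outward-wound triangles.  The raw mesh has 8N vertices and 12N triangles;
#' pass it through [deduplicate()] to weld shared corners and dissolve the
#' interior walls between adjacent cubes.
#'
#' The mesh carries the integer corner-lattice coordinates of its vertices
#' as an attribute so that welding and enclosed-volume computations are
#' exact.
#'
#' @param mask a non-empty [binary_mask()] (e.g. the scar mask).
#' @return An object of class `voxel_cube_mesh`: `mesh` (a [trimesh()]),
#'   `source_voxel_count` and `voxel_spacing`.
#' @export
voxels_to_cubemesh <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  idx <- which(mask$data)
  if (!length(idx)) stop("cannot build a cube mesh: the mask is empty")
  ijk <- arrayInd(idx, dim(mask$data)) - 1L  # 0-based voxel indices
  n <- nrow(ijk)
  corner <- as.matrix(expand.grid(x = c(0L, 1L), y = c(0L, 1L), z = c(0L, 1L)))
  # lattice corners: voxel (i,j,k) spans lattice [i, i+1] x [j, j+1] x [k, k+1]
  lat <- matrix(0L, 8L * n, 3L)
  for (c in 1:8)
    lat[seq(c, by = 8L, length.out = n), ] <- sweep(ijk, 2, corner[c, ], "+")
  base_f <- cube_face_triangles()
  off <- rep((0:(n - 1)) * 8L, each = 12L)
  faces <- base_f[rep(1:12, n), ] + off
  grid <- mask$grid
  world <- cbind((lat[, 1] - 0.5) , (lat[, 2] - 0.5), (lat[, 3] - 0.5), 1) %*%
    t(grid$affine)
  mesh <- trimesh(world[, 1:3, drop = FALSE], faces)
  attr(mesh, "lattice") <- lat
  attr(mesh, "lattice_spacing") <- grid$spacing
  structure(list(mesh = mesh, source_voxel_count = n,
                 voxel_spacing = grid$spacing),
            class = "voxel_cube_mesh")
}

#' @export
print.voxel_cube_mesh <- function(x, ...) {
  cat("<voxel_cube_mesh> ", x$source_voxel_count, " voxels @ ",
      paste(x$voxel_spacing, collapse = "x"), " mm; ", sep = "")
  print(x$mesh)
  invisible(x)
}

#' Remove duplicated vertices and faces
#'
#' Vertices within `weld_tolerance` of each other are merged (cube meshes
#' weld exactly through their integer lattice coordinates).  Faces with an
#' identical vertex set -- regardless of order or winding -- that occur more
#' than once are all removed by default, so the interior walls between
#' adjacent cubes vanish and the boundary shell remains; `keep_one = TRUE`
#' retains a single copy instead.  Faces degenerated by the weld are
#' dropped.  The operation is idempotent.
#'
#' @param mesh a [trimesh()] or [voxels_to_cubemesh()] result.
#' @param weld_tolerance vertex welding tolerance in mm.
#' @param keep_one keep one copy of each duplicated face instead of
#'   removing all copies.
#' @return A [trimesh()] (boundary shell for cube meshes).
#' @export
deduplicate <- function(mesh, weld_tolerance = 1e-6, keep_one = FALSE) {
  if (inherits(mesh, "voxel_cube_mesh")) mesh <- mesh$mesh
  stopifnot(inherits(mesh, "trimesh"))
  lat <- attr(mesh, "lattice")
  grp <- if (!is.null(lat)) {
    key <- paste(lat[, 1], lat[, 2], lat[, 3])
    match(key, unique(key))
  } else {
    cpp_weld_groups(mesh$vertices, weld_tolerance)
  }
  first <- !duplicated(grp)
  verts <- mesh$vertices[first, , drop = FALSE]
  faces <- matrix(grp[mesh$faces], ncol = 3)
  ok <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
        faces[, 1] != faces[, 3]
  faces <- faces[ok, , drop = FALSE]
  m1 <- pmin(faces[, 1], faces[, 2], faces[, 3])
  m3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  m2 <- faces[, 1] + faces[, 2] + faces[, 3] - m1 - m3
  fid <- match(paste(m1, m2, m3), unique(paste(m1, m2, m3)))
  keep <- if (keep_one) !duplicated(fid) else tabulate(fid)[fid] == 1L
  faces <- faces[keep, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
  out <- trimesh(verts[used, , drop = FALSE], matrix(remap[faces], ncol = 3),
                 vertex_colors = if (!is.null(mesh$vertex_colors))
                   mesh$vertex_colors[first, , drop = FALSE][used, , drop = FALSE],
                 material = mesh$material)
  if (!is.null(lat)) {
    attr(out, "lattice") <- lat[first, , drop = FALSE][used, , drop = FALSE]
    attr(out, "lattice_spacing") <- attr(mesh, "lattice_spacing")
  }
  out
}

#' Scar mesh from a mask in one call
#'
#' [voxels_to_cubemesh()] followed by [deduplicate()].
#'
#' @param mask a non-empty [binary_mask()].
#' @return The boundary-shell [trimesh()] of the voxel set.
#' @export
scar_mesh_from_mask <- function(mask) deduplicate(voxels_to_cubemesh(mask))
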