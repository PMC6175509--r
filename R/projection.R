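#' Project subendocardial scar onto the endocardial surface
#'
#' Only scar voxels in the subendocardial layer (transmural depth < 1/3)
#' influence the map.  In `binary` mode a vertex is scar-positive iff at
#' least one subendocardial scar voxel centre lies within `radius` of it; in
#' `graded` mode the vertex value is the scar fraction among the
#' subendocardial myocardium voxels within the radius (0 when none are in
#' range), which is the less boundary-biased choice for quantification.
#'
#' The scar area fraction is the face-area-weighted mean of the vertex
#' values: a face contributes the mean of its three vertex indicators (or
#' graded values) times its area.
#'
#' @param endo_mesh endocardial [trimesh()] in the volume's world frame.
#' @param scar a [binary_mask()] of scar voxels.
#' @param layers a [layer_labels()] field on the same grid.
#' @param radius search radius in mm (> 0); default twice the largest voxel
#'   spacing.
#' @param mode `"binary"` or `"graded"`.
#' @return An object of class `surface_scar_map`: `mesh`, `vertex_scar`
#'   (0/1 or graded in \[0, 1\]), `scar_area_fraction`, `mode`, `radius`.
#' @export
project_scar <- function(endo_mesh, scar, layers, radius = NULL,
                         mode = c("binary", "graded")) {
  mode <- match.arg(mode)
  stopifnot(inherits(endo_mesh, "trimesh"), inherits(scar, "binary_mask"),
            inherits(layers, "layer_label_field"))
  if (is.null(radius)) radius <- 2 * max(scar$grid$spacing)
  if (radius <= 0) stop("radius must be positive")
  d <- dim(scar$data)
  if (!all(dim(unclass(layers)) == d))
    stop("layer field and scar mask are on different grids")
  subendo <- unclass(layers) == 1L
  sub_scar_idx <- which(subendo & scar$data)
  V <- endo_mesh$vertices
  if (!length(sub_scar_idx)) {
    vertex_scar <- numeric(nrow(V))
  } else {
    p_scar <- voxel_centers(scar$grid, arrayInd(sub_scar_idx, d) - 1L)
    n_scar <- cpp_radius_count(p_scar, V, radius)
    if (mode == "binary") {
      vertex_scar <- as.numeric(n_scar > 0)
    } else {
      sub_idx <- which(subendo)
      p_sub <- voxel_centers(scar$grid, arrayInd(sub_idx, d) - 1L)
      n_sub <- cpp_radius_count(p_sub, V, radius)
      vertex_scar <- ifelse(n_sub > 0, n_scar / pmax(n_sub, 1L), 0)
    }
  }
  structure(list(mesh = endo_mesh, vertex_scar = vertex_scar,
                 scar_area_fraction = area_fraction(endo_mesh, vertex_scar),
                 mode = mode, radius = radius),
            class = "surface_scar_map")
}

area_fraction <- function(mesh, vertex_values) {
  if (nrow(mesh$faces) == 0) return(0)
  a <- face_areas(mesh)
  share <- (vertex_values[mesh$faces[, 1]] + vertex_values[mesh$faces[, 2]] +
            vertex_values[mesh$faces[, 3]]) / 3
  sum(share * a) / sum(a)
}

#' @export
print.surface_scar_map <- function(x, ...) {
  cat("<surface_scar_map> (", x$mode, ", radius ", signif(x$radius, 3),
      " mm): ", sum(x$vertex_scar > 0), "/", length(x$vertex_scar),
      " vertices touched, scar area fraction ",
      signif(100 * x$scar_area_fraction, 3), "%\n", sep = "")
  invisible(x)
}

#' Colour the endocardial mesh by projected scar
#'
#' Scar-positive vertices get `scar_color`, the rest `remote_color`; graded
#' values interpolate linearly between the two.
#'
#' @param map a [project_scar()] result.
#' @param scar_color,remote_color RGB triples in \[0, 1\].
#' @param alpha opacity written into the vertex colours.
#' @return The endocardial [trimesh()] with per-vertex RGBA colours.
#' @export
vertex_colors_from_map <- function(map, scar_color = c(1, 0.9, 0.2),
                                   remote_color = c(0.65, 0.3, 0.25),
                                   alpha = 1) {
  stopifnot(inherits(map, "surface_scar_map"))
  t <- pmin(pmax(map$vertex_scar, 0), 1)
  cols <- cbind(outer(t, scar_color) + outer(1 - t, remote_color), alpha)
  m <- map$mesh
  m$vertex_colors <- cols
  m
}

#' Bake the scar map to a texture with a fold-free UV parametrisation
#'
#' Parametrises the (basally clipped, disk-like) endocardial mesh by a
#' Tutte barycentric embedding: the boundary loop is mapped to a circle by
#' arc length and every interior vertex is placed at the average of its
#' neighbours (a sparse Laplace solve), which is guaranteed fold-free for a
#' mesh homeomorphic to a disk.  Texels are rasterised from the per-vertex
#' scar colours by barycentric interpolation.
#'
#' @param map a [project_scar()] result (single-component mesh).
#' @param resolution texture edge length in pixels (default 512).
#' @param scar_color,remote_color RGB triples in \[0, 1\].
#' @return `list(texture, uv)`: a resolution x resolution x 3 array in
#'   \[0, 1\] and a V x 2 matrix of per-vertex UV coordinates.
#' @export
bake_texture <- function(map, resolution = 512, scar_color = c(1, 0.9, 0.2),
                         remote_color = c(0.65, 0.3, 0.25)) {
  stopifnot(inherits(map, "surface_scar_map"))
  mesh <- map$mesh
  if (nrow(mesh$faces) == 0) stop("cannot parametrise an empty mesh")
  if (max(cpp_edge_counts(mesh$faces)) > 2L)
    stop("cannot parametrise a non-manifold mesh")
  if (max(mesh_components(mesh)) > 1L)
    stop("cannot parametrise a multi-component mesh")
  uv <- tutte_parametrization(mesh)

  t <- pmin(pmax(map$vertex_scar, 0), 1)
  vcol <- outer(t, scar_color) + outer(1 - t, remote_color)
  tex <- array(rep(remote_color, each = resolution * resolution),
               dim = c(resolution, resolution, 3))
  px <- uv * (resolution - 1) + 1  # texel coordinates of the vertices
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[f, ]
    a <- px[tri[1], ]; b <- px[tri[2], ]; c <- px[tri[3], ]
    i0 <- max(1, floor(min(a[1], b[1], c[1]))); i1 <- min(resolution, ceiling(max(a[1], b[1], c[1])))
    j0 <- max(1, floor(min(a[2], b[2], c[2]))); j1 <- min(resolution, ceiling(max(a[2], b[2], c[2])))
    if (i1 < i0 || j1 < j0) next
    gi <- seq(i0, i1); gj <- seq(j0, j1)
    pts <- cbind(rep(gi, length(gj)), rep(gj, each = length(gi)))
    det <- (b[1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-12) next
    w1 <- ((pts[, 1] - a[1]) * (c[2] - a[2]) - (c[1] - a[1]) * (pts[, 2] - a[2])) / det
    w2 <- ((b[1] - a[1]) * (pts[, 2] - a[2]) - (pts[, 1] - a[1]) * (b[2] - a[2])) / det
    w0 <- 1 - w1 - w2
    inside <- w0 >= -1e-9 & w1 >= -1e-9 & w2 >= -1e-9
    if (!any(inside)) next
    cols <- w0[inside] %o% vcol[tri[1], ] + w1[inside] %o% vcol[tri[2], ] +
            w2[inside] %o% vcol[tri[3], ]
    sel <- pts[inside, , drop = FALSE]
    for (ch in 1:3)
      tex[cbind(sel, ch)] <- cols[, ch]
  }
  list(texture = tex, uv = uv)
}

# Tutte barycentric disk embedding: boundary loop on the unit circle by arc
# length, interior vertices at the uniform average of their neighbours.
tutte_parametrization <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V)
  # undirected edges with incidence counts
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2]); hi <- pmax(e[, 1], e[, 2])
  key <- lo * (nv + 1) + hi
  tab <- table(key)
  boundary_keys <- as.numeric(names(tab)[tab == 1L])
  if (!length(boundary_keys))
    stop("mesh is closed; a disk parametrisation needs a boundary ",
         "(clip the mesh at the base first)")
  b_lo <- floor(boundary_keys / (nv + 1)); b_hi <- boundary_keys %% (nv + 1)
  # walk the boundary loop
  nbr <- split(c(b_hi, b_lo), c(b_lo, b_hi))
  start <- b_lo[1]
  loop <- c(start)
  prev <- -1; cur <- start
  repeat {
    nxt <- setdiff(nbr[[as.character(cur)]], prev)[1]
    if (is.na(nxt)) stop("mesh boundary is not a closed loop")
    if (nxt == start) break
    loop <- c(loop, nxt)
    prev <- cur; cur <- nxt
    if (length(loop) > length(boundary_keys)) break
  }
  if (length(loop) != length(unique(c(b_lo, b_hi))))
    stop("mesh is not a topological disk (multiple boundary loops)")
  # boundary on a circle, spaced by arc length
  seg <- sqrt(rowSums((V[loop, , drop = FALSE] -
                       V[c(loop[-1], loop[1]), , drop = FALSE])^2))
  theta <- 2 * pi * cumsum(c(0, seg[-length(seg)])) / sum(seg)
  uv <- matrix(NA_real_, nv, 2)
  uv[loop, ] <- 0.5 + 0.48 * cbind(cos(theta), sin(theta))
  interior <- setdiff(seq_len(nv), loop)
  if (length(interior)) {
    idx <- integer(nv); idx[interior] <- seq_along(interior)
    ii <- c(e[, 1], e[, 2]); jj <- c(e[, 2], e[, 1])
    keep <- ii %in% interior
    ii <- ii[keep]; jj <- jj[keep]
    deg <- tabulate(idx[ii], nbins = length(interior)) / 2  # each edge twice
    to_int <- jj %in% interior
    A <- Matrix::sparseMatrix(i = idx[ii[to_int]], j = idx[jj[to_int]],
                              x = -0.5,  # halved: every edge appears twice
                              dims = rep(length(interior), 2)) +
         Matrix::Diagonal(length(interior), deg)
    rhs_i <- idx[ii[!to_int]]
    b_u <- rep(0, length(interior)); b_v <- rep(0, length(interior))
    for (t in seq_along(rhs_i)) {
      b_u[rhs_i[t]] <- b_u[rhs_i[t]] + 0.5 * uv[jj[!to_int][t], 1]
      b_v[rhs_i[t]] <- b_v[rhs_i[t]] + 0.5 * uv[jj[!to_int][t], 2]
    }
    uv[interior, 1] <- as.numeric(Matrix::solve(A, b_u))
    uv[interior, 2] <- as.numeric(Matrix::solve(A, b_v))
  }
  uv
}

#' Write a baked texture as PNG
#'
#' @param baked result of [bake_texture()].
#' @param path output .png path.
#' @return `path`, invisibly.
#' @export
write_texture_png <- function(baked, path) {
  # image rows run top-to-bottom; flip V so the texture reads naturally
  img <- aperm(baked$texture[, dim(baked$texture)[2]:1, , drop = FALSE],
               c(2, 1, 3))
  png::writePNG(img, path)
  invisible(path)
}
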