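MESH_FORMATS <- c("obj", "ply", "gltf", "glb")

mesh_format_from_path <- function(path, format = NULL) {
  if (!is.null(format)) {
    format <- tolower(format)
    if (!format %in% MESH_FORMATS)
      stop("unsupported mesh format '", format, "'; supported: ",
           paste(MESH_FORMATS, collapse = ", "))
    return(format)
  }
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% MESH_FORMATS)
    stop("unsupported mesh format '.", ext, "'; supported: ",
         paste(MESH_FORMATS, collapse = ", "))
  ext
}

#' Write a triangle mesh to OBJ, PLY or glTF/GLB
#'
#' OBJ carries per-vertex colors as the widely supported 6-number `v` line
#' extension and materials through a sidecar MTL file (`Kd` diffuse color,
#' `d` opacity).  PLY is written binary little-endian with per-vertex uchar
#' RGBA.  glTF/GLB store positions and indices in a binary buffer with
#' per-vertex `COLOR_0` and a PBR material whose `alphaMode` is `BLEND` for
#' transparent layers.
#'
#' @param mesh a [trimesh()].
#' @param path output path; extension selects the format unless `format`
#'   is given.
#' @param format one of `"obj"`, `"ply"`, `"gltf"`, `"glb"` (optional).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "trimesh"))
  format <- mesh_format_from_path(path, format)
  switch(format,
         obj = write_obj_scene(scene_of(mesh), path),
         ply = write_ply(mesh, path),
         gltf = write_gltf_scene(scene_of(mesh), path, binary = FALSE),
         glb = write_gltf_scene(scene_of(mesh), path, binary = TRUE))
  invisible(path)
}

# wrap a bare mesh as a single-layer scene for the scene-level writers
scene_of <- function(mesh) {
  mat <- mesh$material
  layered_scene(list(list(
    name = if (!is.null(mat)) mat$name else "mesh",
    mesh = mesh,
    color = if (!is.null(mat)) mat$color else c(0.8, 0.8, 0.8),
    alpha = if (!is.null(mat)) mat$alpha else 1)))
}

#' Read a triangle mesh from OBJ, PLY or glTF/GLB
#'
#' @param path mesh file.
#' @return A [trimesh()]; multi-layer files give an error pointing to
#'   [read_scene()].
#' @export
read_mesh <- function(path) {
  sc <- read_scene(path)
  if (length(sc$layers) != 1L)
    stop("file contains ", length(sc$layers),
         " layers; use read_scene() to load them all")
  layer_mesh(sc$layers[[1]])
}

layer_mesh <- function(layer) {
  m <- layer$mesh
  m$material <- list(color = layer$color, alpha = layer$alpha,
                     name = layer$name)
  m
}

## ---- OBJ -------------------------------------------------------------

write_obj_scene <- function(scene, path) {
  mtl_path <- sub("\\.[Oo][Bb][Jj]$", ".mtl", path)
  if (mtl_path == path) mtl_path <- paste0(path, ".mtl")
  obj <- c("# exported by scarmesh", paste("mtllib", basename(mtl_path)))
  mtl <- character()
  voffset <- 0L
  for (layer in scene$layers) {
    m <- layer$mesh
    mtl <- c(mtl, paste("newmtl", layer$name),
             sprintf("Kd %.6f %.6f %.6f", layer$color[1], layer$color[2],
                     layer$color[3]),
             sprintf("d %.6f", layer$alpha), "illum 1", "")
    obj <- c(obj, paste("o", layer$name), paste("usemtl", layer$name))
    if (is.null(m$vertex_colors)) {
      obj <- c(obj, sprintf("v %.9g %.9g %.9g", m$vertices[, 1],
                            m$vertices[, 2], m$vertices[, 3]))
    } else {
      obj <- c(obj, sprintf("v %.9g %.9g %.9g %.6f %.6f %.6f",
                            m$vertices[, 1], m$vertices[, 2], m$vertices[, 3],
                            m$vertex_colors[, 1], m$vertex_colors[, 2],
                            m$vertex_colors[, 3]))
    }
    obj <- c(obj, sprintf("f %d %d %d", m$faces[, 1] + voffset,
                          m$faces[, 2] + voffset, m$faces[, 3] + voffset))
    voffset <- voffset + nrow(m$vertices)
  }
  writeLines(obj, path)
  writeLines(mtl, mtl_path)
  invisible(path)
}

read_obj_scene <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tok1 <- sub("^\\s*(\\S+).*", "\\1", lines)
  materials <- list()
  mtl_line <- lines[tok1 == "mtllib"]
  if (length(mtl_line)) {
    mtl_path <- file.path(dirname(path),
                          sub("^\\s*mtllib\\s+", "", mtl_line[1]))
    if (file.exists(mtl_path)) materials <- read_mtl(mtl_path)
  }
  vlines <- strsplit(trimws(lines[tok1 == "v"]), "\\s+")
  nums <- lapply(vlines, function(x) as.numeric(x[-1]))
  verts <- do.call(rbind, lapply(nums, function(x) x[1:3]))
  vcols <- NULL
  if (all(lengths(nums) >= 6))
    vcols <- cbind(do.call(rbind, lapply(nums, function(x) x[4:6])), 1)

  cur_mat <- "default"
  face_rows <- list(); face_mat <- character()
  for (ln in lines[tok1 %in% c("usemtl", "f")]) {
    if (startsWith(trimws(ln), "usemtl")) {
      cur_mat <- sub("^\\s*usemtl\\s+", "", ln)
    } else {
      parts <- strsplit(trimws(ln), "\\s+")[[1]][-1]
      idx <- as.integer(sub("/.*", "", parts))
      face_rows[[length(face_rows) + 1L]] <- idx[1:3]
      face_mat <- c(face_mat, cur_mat)
    }
  }
  faces <- do.call(rbind, face_rows)
  layers <- lapply(unique(face_mat), function(mat) {
    f <- faces[face_mat == mat, , drop = FALSE]
    used <- sort(unique(as.vector(f)))
    remap <- integer(nrow(verts)); remap[used] <- seq_along(used)
    m <- trimesh(verts[used, , drop = FALSE], matrix(remap[f], ncol = 3),
                 vertex_colors = if (!is.null(vcols))
                   vcols[used, , drop = FALSE])
    info <- materials[[mat]]
    list(name = mat, mesh = m,
         color = if (!is.null(info)) info$color else c(0.8, 0.8, 0.8),
         alpha = if (!is.null(info)) info$alpha else 1)
  })
  layered_scene(layers)
}

read_mtl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); cur <- NULL
  for (ln in trimws(lines)) {
    if (startsWith(ln, "newmtl")) {
      cur <- sub("^newmtl\\s+", "", ln)
      out[[cur]] <- list(color = c(0.8, 0.8, 0.8), alpha = 1)
    } else if (!is.null(cur) && startsWith(ln, "Kd")) {
      out[[cur]]$color <- as.numeric(strsplit(ln, "\\s+")[[1]][2:4])
    } else if (!is.null(cur) && grepl("^d\\s", ln)) {
      out[[cur]]$alpha <- as.numeric(strsplit(ln, "\\s+")[[1]][2])
    }
  }
  out
}

## ---- PLY -------------------------------------------------------------

write_ply <- function(mesh, path) {
  has_col <- !is.null(mesh$vertex_colors) || !is.null(mesh$material)
  cols <- mesh$vertex_colors
  if (has_col && is.null(cols)) {
    mat <- mesh$material
    cols <- matrix(rep(c(mat$color, mat$alpha), each = nrow(mesh$vertices)),
                   ncol = 4)
  }
  header <- c("ply", "format binary_little_endian 1.0",
              "comment exported by scarmesh")
  if (!is.null(mesh$material))
    header <- c(header, sprintf("comment material %s %.6f %.6f %.6f %.6f",
                                mesh$material$name, mesh$material$color[1],
                                mesh$material$color[2], mesh$material$color[3],
                                mesh$material$alpha))
  header <- c(header,
              paste("element vertex", nrow(mesh$vertices)),
              "property float x", "property float y", "property float z")
  if (has_col)
    header <- c(header, "property uchar red", "property uchar green",
                "property uchar blue", "property uchar alpha")
  header <- c(header, paste("element face", nrow(mesh$faces)),
              "property list uchar int vertex_indices", "end_header")

  pos_raw <- writeBin(as.numeric(t(mesh$vertices)), raw(), size = 4,
                      endian = "little")
  vmat <- matrix(pos_raw, nrow = 12L)
  if (has_col) {
    cmat <- matrix(as.raw(pmin(pmax(round(t(cols) * 255), 0), 255)),
                   nrow = 4L)
    vmat <- rbind(vmat, cmat)
  }
  idx_raw <- writeBin(as.integer(t(mesh$faces) - 1L), raw(), size = 4,
                      endian = "little")
  fmat <- rbind(matrix(as.raw(3), nrow = 1, ncol = nrow(mesh$faces)),
                matrix(idx_raw, nrow = 12L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(as.vector(vmat), con)
  writeBin(as.vector(fmat), con)
  invisible(path)
}

read_ply <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  # header ends at the newline after "end_header"; scan bytes, the body is
  # binary and cannot be converted to a string
  pos <- grepRaw("end_header", raw_all, fixed = TRUE)
  if (!length(pos)) stop("not a PLY file (no end_header): ", path)
  nl <- which(raw_all[pos:min(pos + 16L, length(raw_all))] == as.raw(10L))[1]
  hdr_len <- pos + nl - 1L
  header <- strsplit(rawToChar(raw_all[seq_len(hdr_len)]), "\r?\n")[[1]]
  fmt <- header[grepl("^format", header)][1]
  ascii <- grepl("ascii", fmt)
  nv <- as.integer(sub(".*element vertex (\\d+).*", "\\1",
                       header[grepl("^element vertex", header)][1]))
  nf <- as.integer(sub(".*element face (\\d+).*", "\\1",
                       header[grepl("^element face", header)][1]))
  vprops <- character()
  in_vertex <- FALSE
  for (ln in header) {
    if (startsWith(ln, "element")) in_vertex <- startsWith(ln, "element vertex")
    else if (in_vertex && startsWith(ln, "property"))
      vprops <- c(vprops, ln)
  }
  vnames <- vapply(strsplit(vprops, "\\s+"), function(x) x[3], "")
  vtypes <- vapply(strsplit(vprops, "\\s+"), function(x) x[2], "")
  has_col <- all(c("red", "green", "blue") %in% vnames)

  material <- NULL
  mline <- header[grepl("^comment material ", header)]
  if (length(mline)) {
    parts <- strsplit(mline[1], "\\s+")[[1]]
    material <- list(name = parts[3], color = as.numeric(parts[4:6]),
                     alpha = as.numeric(parts[7]))
  }

  if (ascii) {
    body <- strsplit(rawToChar(raw_all), "\r?\n")[[1]][-seq_along(header)]
    vdat <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                                  as.numeric))
    verts <- vdat[, match(c("x", "y", "z"), vnames), drop = FALSE]
    cols <- if (has_col) {
      ci <- match(c("red", "green", "blue"), vnames)
      ai <- match("alpha", vnames)
      cbind(vdat[, ci, drop = FALSE],
            if (!is.na(ai)) vdat[, ai] else 255) / 255
    }
    fdat <- lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"),
                   as.integer)
    faces <- do.call(rbind, lapply(fdat, function(x) x[2:4])) + 1L
  } else {
    if (!grepl("binary_little_endian", fmt))
      stop("unsupported PLY encoding: ", fmt)
    sizes <- c(float = 4L, double = 8L, uchar = 1L, uint8 = 1L, char = 1L,
               int = 4L, uint = 4L, int32 = 4L, short = 2L, ushort = 2L)
    vsizes <- sizes[vtypes]
    if (any(is.na(vsizes))) stop("unsupported PLY vertex property types")
    stride <- sum(vsizes)
    off <- cumsum(c(0L, vsizes[-length(vsizes)]))
    names(off) <- vnames
    body <- raw_all[(hdr_len + 1L):length(raw_all)]
    vbytes <- matrix(body[seq_len(nv * stride)], nrow = stride)
    getf <- function(name) {
      o <- off[[name]]; tp <- vtypes[match(name, vnames)]
      bytes <- as.vector(vbytes[o + seq_len(sizes[[tp]]), , drop = FALSE])
      if (tp %in% c("float", "double"))
        readBin(bytes, "double", n = nv, size = sizes[[tp]], endian = "little")
      else
        readBin(bytes, "integer", n = nv, size = sizes[[tp]],
                signed = sizes[[tp]] > 1, endian = "little")
    }
    verts <- cbind(getf("x"), getf("y"), getf("z"))
    cols <- if (has_col) {
      a <- if ("alpha" %in% vnames) getf("alpha") else 255
      cbind(getf("red"), getf("green"), getf("blue"), a) / 255
    }
    fb <- body[(nv * stride + 1L):length(body)]
    fmatb <- matrix(fb[seq_len(nf * 13L)], nrow = 13L)
    counts <- as.integer(fmatb[1L, ])
    if (any(counts != 3L)) stop("only triangle PLY faces are supported")
    faces <- matrix(readBin(as.vector(fmatb[-1L, , drop = FALSE]), "integer",
                            n = 3L * nf, size = 4L, endian = "little"),
                    ncol = 3L, byrow = TRUE) + 1L
  }
  m <- trimesh(verts, faces, vertex_colors = cols, material = material)
  layered_scene(list(list(name = if (!is.null(material)) material$name else "mesh",
                          mesh = m,
                          color = if (!is.null(material)) material$color
                                  else c(0.8, 0.8, 0.8),
                          alpha = if (!is.null(material)) material$alpha else 1)))
}

## ---- glTF / GLB ------------------------------------------------------

pad4 <- function(r, fill = as.raw(0)) {
  n <- (4 - length(r) %% 4) %% 4
  c(r, rep(fill, n))
}

gltf_build <- function(scene) {
  buffer <- raw()
  views <- list(); accessors <- list(); materials <- list()
  meshes <- list(); nodes <- list()
  for (li in seq_along(scene$layers)) {
    layer <- scene$layers[[li]]
    m <- layer$mesh
    pos <- as.numeric(t(m$vertices))
    pos_raw <- writeBin(pos, raw(), size = 4, endian = "little")
    idx_raw <- writeBin(as.integer(t(m$faces) - 1L), raw(), size = 4,
                        endian = "little")
    attrs <- list(POSITION = length(accessors))
    views[[length(views) + 1]] <- list(buffer = 0,
                                       byteOffset = length(buffer),
                                       byteLength = length(pos_raw),
                                       target = 34962)
    buffer <- c(buffer, pad4(pos_raw))
    accessors[[length(accessors) + 1]] <- list(
      bufferView = length(views) - 1, componentType = 5126,
      count = nrow(m$vertices), type = "VEC3",
      min = as.numeric(apply(m$vertices, 2, min)),
      max = as.numeric(apply(m$vertices, 2, max)))
    if (!is.null(m$vertex_colors)) {
      col_raw <- writeBin(as.numeric(t(m$vertex_colors)), raw(), size = 4,
                          endian = "little")
      views[[length(views) + 1]] <- list(buffer = 0,
                                         byteOffset = length(buffer),
                                         byteLength = length(col_raw),
                                         target = 34962)
      buffer <- c(buffer, pad4(col_raw))
      attrs$COLOR_0 <- length(accessors)
      accessors[[length(accessors) + 1]] <- list(
        bufferView = length(views) - 1, componentType = 5126,
        count = nrow(m$vertices), type = "VEC4")
    }
    views[[length(views) + 1]] <- list(buffer = 0,
                                       byteOffset = length(buffer),
                                       byteLength = length(idx_raw),
                                       target = 34963)
    buffer <- c(buffer, pad4(idx_raw))
    idx_acc <- length(accessors)
    accessors[[length(accessors) + 1]] <- list(
      bufferView = length(views) - 1, componentType = 5125,
      count = 3L * nrow(m$faces), type = "SCALAR")
    materials[[length(materials) + 1]] <- list(
      name = layer$name,
      pbrMetallicRoughness = list(
        baseColorFactor = as.numeric(c(layer$color, layer$alpha)),
        metallicFactor = 0, roughnessFactor = 1),
      alphaMode = if (layer$alpha < 1) "BLEND" else "OPAQUE",
      doubleSided = TRUE)
    meshes[[length(meshes) + 1]] <- list(
      name = layer$name,
      primitives = list(list(attributes = attrs, indices = idx_acc,
                             material = length(materials) - 1, mode = 4)))
    nodes[[length(nodes) + 1]] <- list(name = layer$name, mesh = li - 1)
  }
  json <- list(
    asset = list(version = "2.0", generator = "scarmesh"),
    scene = 0,
    scenes = list(list(nodes = I(seq_along(nodes) - 1))),
    nodes = nodes,
    meshes = meshes,
    materials = materials,
    accessors = accessors,
    bufferViews = views,
    buffers = list(list(byteLength = length(buffer))))
  list(json = json, buffer = buffer)
}

write_gltf_scene <- function(scene, path, binary = TRUE) {
  built <- gltf_build(scene)
  if (binary) {
    jtxt <- charToRaw(as.character(jsonlite::toJSON(built$json,
                                                    auto_unbox = TRUE,
                                                    digits = NA)))
    jtxt <- pad4(jtxt, charToRaw(" "))
    bin <- pad4(built$buffer)
    total <- 12L + 8L + length(jtxt) + 8L + length(bin)
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("glTF"), con)
    writeBin(c(2L, total), con, size = 4, endian = "little")
    writeBin(length(jtxt), con, size = 4, endian = "little")
    writeBin(charToRaw("JSON"), con)
    writeBin(jtxt, con)
    writeBin(length(bin), con, size = 4, endian = "little")
    writeBin(c(charToRaw("BIN"), as.raw(0)), con)
    writeBin(bin, con)
  } else {
    json <- built$json
    json$buffers[[1]]$uri <- paste0("data:application/octet-stream;base64,",
                                    gsub("\n", "",
                                         jsonlite::base64_enc(built$buffer)))
    writeLines(as.character(jsonlite::toJSON(json, auto_unbox = TRUE,
                                             digits = NA)), path)
  }
  invisible(path)
}

read_gltf_scene <- function(path) {
  if (grepl("\\.glb$", path, ignore.case = TRUE)) {
    raw_all <- readBin(path, "raw", file.info(path)$size)
    if (rawToChar(raw_all[1:4]) != "glTF") stop("not a GLB file: ", path)
    jlen <- readBin(raw_all[13:16], "integer", size = 4, endian = "little")
    json <- jsonlite::fromJSON(rawToChar(raw_all[21:(20 + jlen)]),
                               simplifyVector = FALSE)
    blen <- readBin(raw_all[(21 + jlen):(24 + jlen)], "integer", size = 4,
                    endian = "little")
    buffer <- raw_all[(29 + jlen):(28 + jlen + blen)]
  } else {
    json <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    uri <- json$buffers[[1]]$uri
    if (is.null(uri) || !startsWith(uri, "data:"))
      stop("only embedded glTF buffers are supported")
    buffer <- jsonlite::base64_dec(sub("^data:[^,]*,", "", uri))
  }
  read_accessor <- function(ai) {
    acc <- json$accessors[[ai + 1]]
    bv <- json$bufferViews[[acc$bufferView + 1]]
    off <- (if (is.null(bv$byteOffset)) 0 else bv$byteOffset) +
           (if (is.null(acc$byteOffset)) 0 else acc$byteOffset)
    ncomp <- switch(acc$type, SCALAR = 1L, VEC2 = 2L, VEC3 = 3L, VEC4 = 4L)
    n <- acc$count * ncomp
    bytes <- buffer[(off + 1):(off + n * switch(as.character(acc$componentType),
                                                "5126" = 4L, "5125" = 4L,
                                                "5123" = 2L))]
    vals <- switch(as.character(acc$componentType),
                   "5126" = readBin(bytes, "double", n = n, size = 4,
                                    endian = "little"),
                   "5125" = readBin(bytes, "integer", n = n, size = 4,
                                    endian = "little"),
                   "5123" = readBin(bytes, "integer", n = n, size = 2,
                                    signed = FALSE, endian = "little"))
    if (ncomp == 1L) vals else matrix(vals, ncol = ncomp, byrow = TRUE)
  }
  layers <- lapply(json$meshes, function(mesh) {
    prim <- mesh$primitives[[1]]
    verts <- read_accessor(prim$attributes$POSITION)
    faces <- matrix(read_accessor(prim$indices), ncol = 3, byrow = TRUE) + 1L
    cols <- if (!is.null(prim$attributes$COLOR_0))
      read_accessor(prim$attributes$COLOR_0)
    color <- c(0.8, 0.8, 0.8); alpha <- 1
    name <- if (!is.null(mesh$name)) mesh$name else "mesh"
    if (!is.null(prim$material)) {
      mat <- json$materials[[prim$material + 1]]
      bcf <- unlist(mat$pbrMetallicRoughness$baseColorFactor)
      if (length(bcf) == 4) { color <- bcf[1:3]; alpha <- bcf[4] }
      if (!is.null(mat$name)) name <- mat$name
    }
    list(name = name, mesh = trimesh(verts, faces, vertex_colors = cols),
         color = color, alpha = alpha)
  })
  layered_scene(layers)
}
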