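#' Layered 3D scene
#'
#' An ordered list of named mesh layers, each with an RGB color and an
#' opacity, blended back-to-front by viewers.  Units are mm; +z points
#' toward the cardiac base.
#'
#' @param layers list of `list(name, mesh, color, alpha)` entries.
#' @return An object of class `layered_scene`.
#' @export
layered_scene <- function(layers = list()) {
  names_seen <- character()
  for (layer in layers) {
    stopifnot(inherits(layer$mesh, "trimesh"))
    if (is.null(layer$name)) stop("every layer needs a name")
    if (layer$name %in% names_seen)
      stop("duplicate layer name '", layer$name, "'")
    names_seen <- c(names_seen, layer$name)
    if (layer$alpha < 0 || layer$alpha > 1)
      stop("layer '", layer$name, "': alpha must be in [0, 1]")
  }
  structure(list(layers = layers), class = "layered_scene")
}

#' @export
print.layered_scene <- function(x, ...) {
  cat("<layered_scene> ", length(x$layers), " layer(s)\n", sep = "")
  for (layer in x$layers)
    cat(sprintf("  %-12s %6d V %7d F  alpha %.2f\n", layer$name,
                nrow(layer$mesh$vertices), nrow(layer$mesh$faces),
                layer$alpha))
  invisible(x)
}

#' Add a layer to a scene
#'
#' @param scene a [layered_scene()].
#' @param name unique layer name.
#' @param mesh a [trimesh()].
#' @param color RGB triple in \[0, 1\].
#' @param alpha opacity in \[0, 1\].
#' @return The extended [layered_scene()].
#' @export
add_layer <- function(scene, name, mesh, color = c(0.8, 0.8, 0.8), alpha = 1) {
  layered_scene(c(scene$layers, list(list(name = name, mesh = mesh,
                                          color = color, alpha = alpha))))
}

#' Default layer style
#'
#' Epicardium light gray and strongly transparent, endocardium red-brown and
#' semi-transparent, scar yellow and opaque, so the scar reads through the
#' anatomical shells.
#'
#' @return Named list of `list(color, alpha)` styles.
#' @export
scene_style <- function() {
  list(epicardium = list(color = c(0.62, 0.62, 0.62), alpha = 0.2),
       endocardium = list(color = c(0.65, 0.30, 0.25), alpha = 0.4),
       scar = list(color = c(1.00, 0.90, 0.20), alpha = 1.0))
}

#' Assemble surfaces and scar into a layered scene
#'
#' @param endo,epi optional endo-/epicardial [trimesh()]es.
#' @param scar_mesh optional voxel-wise scar [trimesh()] (or
#'   `voxel_cube_mesh`).
#' @param surface_map optional [project_scar()] result; its colored mesh
#'   replaces the plain endocardium layer.
#' @param style style list as from [scene_style()].
#' @return A [layered_scene()] in epi, endo, scar order.
#' @export
assemble_scene <- function(endo = NULL, epi = NULL, scar_mesh = NULL,
                           surface_map = NULL, style = scene_style()) {
  sc <- layered_scene()
  if (!is.null(epi))
    sc <- add_layer(sc, "epicardium", epi, style$epicardium$color,
                    style$epicardium$alpha)
  if (!is.null(surface_map)) {
    sc <- add_layer(sc, "endocardium", vertex_colors_from_map(surface_map),
                    style$endocardium$color, style$endocardium$alpha)
  } else if (!is.null(endo)) {
    sc <- add_layer(sc, "endocardium", endo, style$endocardium$color,
                    style$endocardium$alpha)
  }
  if (!is.null(scar_mesh)) {
    if (inherits(scar_mesh, "voxel_cube_mesh")) scar_mesh <- scar_mesh$mesh
    sc <- add_layer(sc, "scar", scar_mesh, style$scar$color, style$scar$alpha)
  }
  if (!length(sc$layers)) stop("scene needs at least one layer")
  sc
}

#' Export a layered scene
#'
#' glTF/GLB keep one mesh node per layer with a PBR material
#' (`alphaMode = "BLEND"` for transparent layers); OBJ writes one object
#' group per layer with a sidecar MTL whose `d` entries carry the layer
#' alphas.
#'
#' @param scene a [layered_scene()].
#' @param path output path (.glb, .gltf or .obj).
#' @param format optional explicit format.
#' @return `path`, invisibly.
#' @export
export_scene <- function(scene, path, format = NULL) {
  stopifnot(inherits(scene, "layered_scene"))
  format <- mesh_format_from_path(path, format)
  switch(format,
         glb = write_gltf_scene(scene, path, binary = TRUE),
         gltf = write_gltf_scene(scene, path, binary = FALSE),
         obj = write_obj_scene(scene, path),
         ply = stop("PLY holds a single mesh; use write_mesh() per layer or ",
                    "export the scene as glTF/GLB/OBJ"))
  invisible(path)
}

#' Read a scene (or single mesh file) back
#'
#' @param path .glb, .gltf, .obj or .ply file.
#' @return A [layered_scene()].
#' @export
read_scene <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- mesh_format_from_path(path)
  switch(format,
         glb = read_gltf_scene(path),
         gltf = read_gltf_scene(path),
         obj = read_obj_scene(path),
         ply = read_ply(path))
}

#' Scar-burden metrics
#'
#' Overall scar volume as a percentage of the LV myocardial volume, the
#' subendocardial portion of the scar as a percentage of total scar volume,
#' and the scar area projected on the endocardial surface as a percentage of
#' that surface.
#'
#' @param seg a [fwhm_scar_mask()] result.
#' @param layers a [layer_labels()] field.
#' @param map optional [project_scar()] result (surface percentage is NA
#'   without it).
#' @return An object of class `scar_metrics` with fields
#'   `scar_volume_fraction_of_lv`, `endocardial_scar_fraction_of_total`,
#'   `endocardial_surface_scar_area_fraction` (all percentages).
#' @export
compute_metrics <- function(seg, layers, map = NULL) {
  stopifnot(inherits(seg, "scar_segmentation"),
            inherits(layers, "layer_label_field"))
  n_myo <- sum(seg$myocardium_mask$data)
  n_scar <- sum(seg$scar_mask$data)
  svf <- 100 * n_scar / n_myo
  if (n_scar == 0) {
    warning("no scar voxels: the endocardial portion of scar is undefined")
    esf <- NaN
  } else {
    esf <- 100 * sum(seg$scar_mask$data & unclass(layers) == 1L) / n_scar
  }
  ssf <- if (!is.null(map)) 100 * map$scar_area_fraction else NA_real_
  structure(list(scar_volume_fraction_of_lv = svf,
                 endocardial_scar_fraction_of_total = esf,
                 endocardial_surface_scar_area_fraction = ssf),
            class = "scar_metrics")
}

#' @export
print.scar_metrics <- function(x, ...) {
  cat("<scar_metrics>\n")
  cat(sprintf("  scar volume:            %5.1f %% of LV myocardium\n",
              x$scar_volume_fraction_of_lv))
  cat(sprintf("  endocardial portion:    %5.1f %% of total scar\n",
              x$endocardial_scar_fraction_of_total))
  cat(sprintf("  surface-projected area: %5.1f %% of endocardial surface\n",
              x$endocardial_surface_scar_area_fraction))
  invisible(x)
}
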