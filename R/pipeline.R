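#' Full scar-modelling pipeline
#'
#' Runs the complete chain on a volume and its contours: myocardium
#' rasterisation, FWHM scar segmentation, endo-/epicardial surface
#' reconstruction, transmural depth and layer partition, voxel-wise scar
#' cube mesh with deduplication, subendocardial surface projection,
#' scar-burden metrics and the layered export scene.
#'
#' @param volume an [lge_volume()].
#' @param contours a [contour_set()] with `lv_endo` and `lv_epi` records.
#' @param decimation_cell point-cloud decimation cell in mm; default twice
#'   the in-plane voxel spacing.
#' @param recon_depth grid resolution exponent of the surface
#'   reconstruction (default 7).
#' @param projection_radius radius of the scar projection search in mm;
#'   default twice the largest voxel spacing.
#' @param projection_mode `"graded"` (default, used for quantification) or
#'   `"binary"`.
#' @param clip_surfaces clip the reconstructed surfaces at the most basal
#'   contoured slice for the export scene (default TRUE).
#' @param reference_region,percentile passed to [fwhm_scar_mask()].
#' @param style layer style for [assemble_scene()].
#' @return An object of class `scar_model`: `segmentation`, `depth`,
#'   `layers`, `endo_mesh`, `epi_mesh`, `scar_mesh`, `surface_map`,
#'   `metrics`, `scene`.
#' @export
scar_pipeline <- function(volume, contours,
                          decimation_cell = NULL,
                          recon_depth = 7,
                          projection_radius = NULL,
                          projection_mode = "graded",
                          clip_surfaces = TRUE,
                          reference_region = NULL,
                          percentile = 1,
                          style = scene_style()) {
  stopifnot(inherits(volume, "lge_volume"), inherits(contours, "contour_set"))
  if (is.null(decimation_cell)) decimation_cell <- 2 * max(volume$spacing[1:2])

  myo <- myocardium_mask_from_contours(contours, volume)
  seg <- fwhm_scar_mask(volume, myo, reference_region = reference_region,
                        percentile = percentile)

  endo_mesh <- surface_from_contours(contours, "lv_endo", volume,
                                     cell_size = decimation_cell,
                                     depth = recon_depth)
  epi_mesh <- surface_from_contours(contours, "lv_epi", volume,
                                    cell_size = decimation_cell,
                                    depth = recon_depth)

  # clip before measuring depth: the reconstruction's artificial closure
  # above the basal rim must not attract distance queries
  plane <- basal_plane(contours, volume,
                       offset_mm = volume$spacing[3] / 2)
  endo_clip <- if (clip_surfaces) clip_at_base(endo_mesh, plane) else endo_mesh
  epi_clip <- if (clip_surfaces) clip_at_base(epi_mesh, plane) else epi_mesh

  depth <- transmural_depth_field(myo, endo_clip, epi_clip)
  seg$transmural_depth <- depth
  layers <- layer_labels(depth)

  scar_mesh <- if (any(seg$scar_mask$data))
    scar_mesh_from_mask(seg$scar_mask)

  map <- project_scar(endo_clip, seg$scar_mask, layers,
                      radius = projection_radius, mode = projection_mode)
  metrics <- compute_metrics(seg, layers, map)
  scene <- assemble_scene(epi = epi_clip, scar_mesh = scar_mesh,
                          surface_map = map, style = style)

  structure(list(segmentation = seg, depth = depth, layers = layers,
                 endo_mesh = endo_clip, epi_mesh = epi_clip,
                 endo_mesh_closed = endo_mesh, epi_mesh_closed = epi_mesh,
                 scar_mesh = scar_mesh, surface_map = map,
                 metrics = metrics, scene = scene),
            class = "scar_model")
}

#' @export
print.scar_model <- function(x, ...) {
  cat("<scar_model>\n")
  print(x$segmentation)
  if (!is.null(x$scar_mesh)) {
    st <- mesh_statistics(x$scar_mesh)
    cat("  scar mesh: ", st$vertices, " vertices, ", st$faces, " faces, ",
        signif(st$volume_mm3, 5), " mm^3 in ", st$components,
        " component(s)\n", sep = "")
  }
  print(x$metrics)
  invisible(x)
}
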