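#' Rasterise endo/epi contours into a myocardium mask
#'
#' A voxel belongs to the myocardium iff its centre lies inside the
#' epicardial polygon of its slice and outside the endocardial polygon
#' (even-odd rule; centres exactly on an edge count as inside).  A slice with
#' an epicardial contour but no endocardial one (apical cap) contributes the
#' full epicardial disk; a slice with an endocardial contour but no
#' epicardial one is an error.
#'
#' @param contours a [contour_set()].
#' @param grid an [lge_volume()] defining the voxel grid; the in-plane axes
#'   of its affine must be axis-aligned.
#' @param endo,epi surface labels to use (defaults `lv_endo`, `lv_epi`).
#' @return A [binary_mask()].
#' @export
myocardium_mask_from_contours <- function(contours, grid,
                                          endo = "lv_endo", epi = "lv_epi") {
  stopifnot(inherits(contours, "contour_set"), inherits(grid, "lge_volume"))
  aff <- grid$affine
  if (any(abs(aff[1:2, 3]) > 1e-9) || any(abs(aff[3, 1:2]) > 1e-9))
    stop("contour rasterisation requires slice planes normal to the grid z axis")
  d <- dim(grid$data)
  xs <- aff[1, 4] + aff[1, 1] * (0:(d[1] - 1)) + aff[1, 2] * 0
  ys <- aff[2, 4] + aff[2, 2] * (0:(d[2] - 1))
  if (abs(aff[1, 2]) > 1e-9 || abs(aff[2, 1]) > 1e-9)
    stop("contour rasterisation requires axis-aligned in-plane sampling")

  by_slice <- list()
  for (r in contours$records) {
    if (!r$surface %in% c(endo, epi)) next
    key <- as.character(r$slice)
    if (r$slice < 0 || r$slice >= d[3])
      stop("contour slice index ", r$slice, " outside volume extent [0, ",
           d[3] - 1, "]")
    by_slice[[key]] <- c(by_slice[[key]], list(r))
  }
  mask <- array(FALSE, d)
  for (key in names(by_slice)) {
    k <- as.integer(key)
    recs <- by_slice[[key]]
    labs <- vapply(recs, function(r) r$surface, "")
    if (endo %in% labs && !epi %in% labs)
      stop("slice ", k, " has an endocardial contour but no epicardial one")
    inside_epi <- array(FALSE, d[1:2])
    for (r in recs[labs == epi])
      inside_epi <- inside_epi | cpp_pip_grid(r$points, xs, ys)
    inside_endo <- array(FALSE, d[1:2])
    for (r in recs[labs == endo]) {
      pin <- cpp_pip_grid(r$points, xs, ys)
      if (any(pin & !inside_epi))
        warning("slice ", k, ": endocardial contour not contained in the ",
                "epicardial contour; set difference still applied")
      inside_endo <- inside_endo | pin
    }
    mask[, , k + 1] <- inside_epi & !inside_endo
  }
  binary_mask(mask, grid)
}

#' FWHM scar segmentation
#'
#' Classifies myocardial voxels as scar when their signal intensity exceeds
#' half of a reference maximum (full width at half maximum): the maximum
#' intensity over the myocardium by default, over a user-supplied
#' hyperenhanced reference region if given, optionally robustified to a
#' percentile of the reference intensities.
#'
#' @param volume an [lge_volume()].
#' @param myocardium a [binary_mask()] of the myocardium (non-empty).
#' @param reference_region optional [binary_mask()] from which the reference
#'   maximum is taken instead of the whole myocardium.
#' @param percentile quantile of the reference intensities used as the
#'   reference maximum; default 1 (the plain maximum).
#' @return An object of class `scar_segmentation`: `myocardium_mask`,
#'   `scar_mask`, `threshold` (= 0.5 x reference maximum), `reference_max`,
#'   and `transmural_depth` (NULL until [transmural_depth_field()] fills it).
#' @export
fwhm_scar_mask <- function(volume, myocardium, reference_region = NULL,
                           percentile = 1) {
  stopifnot(inherits(volume, "lge_volume"), inherits(myocardium, "binary_mask"))
  if (!any(myocardium$data)) stop("myocardium mask is empty")
  ref_vals <- if (is.null(reference_region)) volume$data[myocardium$data]
              else volume$data[reference_region$data]
  if (!length(ref_vals)) stop("reference region is empty")
  reference_max <- if (percentile >= 1) max(ref_vals)
                   else as.numeric(quantile(ref_vals, percentile, names = FALSE))
  threshold <- 0.5 * reference_max
  scar <- myocardium$data & volume$data > threshold
  if (all(scar[myocardium$data]))
    warning("degenerate contrast: every myocardial voxel exceeds the FWHM ",
            "threshold")
  structure(list(myocardium_mask = myocardium,
                 scar_mask = binary_mask(scar, myocardium$grid),
                 threshold = threshold, reference_max = reference_max,
                 transmural_depth = NULL),
            class = "scar_segmentation")
}

#' @export
print.scar_segmentation <- function(x, ...) {
  nm <- sum(x$myocardium_mask$data); ns <- sum(x$scar_mask$data)
  cat("<scar_segmentation> ", ns, " scar / ", nm, " myocardial voxels (",
      signif(100 * ns / nm, 3), "%), FWHM threshold ",
      signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Transmural depth field
#'
#' For each myocardial voxel centre p, depth(p) = d_endo(p) / (d_endo(p) +
#' d_epi(p)), the unsigned Euclidean distances to the endo- and epicardial
#' surface meshes: 0 at the endocardium, 1 at the epicardium.  Voxels outside
#' the myocardium are NaN.
#'
#' @param myocardium a [binary_mask()] (or a `scar_segmentation`, whose
#'   myocardium mask is used).
#' @param endo_surface,epi_surface [trimesh()] surfaces enclosing the wall.
#' @return A 3D array of depths in \[0, 1\] (NaN outside the myocardium).
#' @export
transmural_depth_field <- function(myocardium, endo_surface, epi_surface) {
  if (inherits(myocardium, "scar_segmentation"))
    myocardium <- myocardium$myocardium_mask
  stopifnot(inherits(myocardium, "binary_mask"))
  d <- dim(myocardium$data)
  idx <- which(myocardium$data)
  depth <- array(NaN, d)
  if (!length(idx)) return(depth)
  ijk <- arrayInd(idx, d) - 1L
  p <- voxel_centers(myocardium$grid, ijk)
  de <- point_mesh_distance(p, endo_surface)
  dp <- point_mesh_distance(p, epi_surface)
  s <- de + dp
  zero <- s == 0
  if (any(zero)) {
    warning("endo and epi surfaces touch at ", sum(zero),
            " voxel centre(s); depth set to 0 there")
    s[zero] <- 1
    de[zero] <- 0
  }
  depth[idx] <- de / s
  depth
}

LAYER_LEVELS <- c(outside = 0L, subendo = 1L, mid = 2L, subepi = 3L)

#' Partition the myocardium into transmural thirds
#'
#' Subendocardial: depth in \[0, 1/3); mid: \[1/3, 2/3); subepicardial:
#' \[2/3, 1\].  The intervals are half-open with the last closed, so a depth
#' of exactly 1/3 is mid and a depth of exactly 1 is subepicardial.
#'
#' @param depth depth array from [transmural_depth_field()].
#' @return An object of class `layer_label_field`: an integer array with
#'   codes 0 = outside, 1 = subendo, 2 = mid, 3 = subepi.
#' @export
layer_labels <- function(depth) {
  lab <- array(0L, dim(depth))
  inside <- is.finite(depth)
  d <- depth[inside]
  lab[inside] <- ifelse(d < 1 / 3, 1L, ifelse(d < 2 / 3, 2L, 3L))
  structure(lab, class = "layer_label_field", levels = LAYER_LEVELS)
}

#' @export
print.layer_label_field <- function(x, ...) {
  tab <- table(factor(unclass(x), levels = LAYER_LEVELS,
                      labels = names(LAYER_LEVELS)))
  cat("<layer_label_field>\n")
  print(tab)
  invisible(x)
}
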