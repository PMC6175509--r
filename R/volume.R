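#' LGE intensity volume
#'
#' A 3D scalar intensity grid with voxel spacing and a voxel-to-world affine.
#' Voxel indices are 0-based and a voxel's world position refers to its
#' centre; the cuboid rendered for a voxel spans +/- spacing/2 about that
#' centre.
#'
#' @param data 3D numeric array of signal intensities (arbitrary units).
#' @param spacing numeric length-3, voxel spacing (dx, dy, dz) in mm.
#' @param affine 4x4 voxel-index-to-world-mm transform (0-based indices).
#'   Defaults to `diag(spacing)` with the origin at (0, 0, 0).
#' @return An object of class `lge_volume`.
#' @export
lge_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (is.null(affine)) affine <- make_affine(spacing)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "lge_volume")
}

make_affine <- function(spacing, origin = c(0, 0, 0)) {
  a <- diag(c(spacing, 1))
  a[1:3, 4] <- origin
  a
}

#' @export
print.lge_volume <- function(x, ...) {
  cat("<lge_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.lge_volume <- function(x) dim(x$data)

#' World coordinates of voxel centres
#'
#' @param vol an [lge_volume()] (or `binary_mask`) supplying the affine.
#' @param ijk integer matrix (n x 3) of 0-based voxel indices; if `NULL`,
#'   all voxels in grid order.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_centers <- function(vol, ijk = NULL) {
  if (inherits(vol, "binary_mask")) vol <- vol$grid
  d <- dim(vol$data)
  if (is.null(ijk)) {
    ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
  }
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  xyz1 <- cbind(ijk, 1) %*% t(vol$affine)
  xyz1[, 1:3, drop = FALSE]
}

#' Read a medical image volume
#'
#' Reads a NIfTI (.nii/.nii.gz) volume; spacing is taken from the header
#' pixdim and the affine from the sform/qform.
#'
#' @param path path to a NIfTI file.
#' @return An [lge_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable volume file: ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions")
  lge_volume(array(as.numeric(img), dim = d),
             spacing = RNifti::pixdim(img)[1:3],
             affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a volume (or mask) to NIfTI
#'
#' @param vol an [lge_volume()] or [binary_mask()].
#' @param path output path ending in .nii or .nii.gz.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (inherits(vol, "binary_mask")) {
    dat <- array(as.numeric(vol$data), dim = dim(vol$data))
    vol <- lge_volume(dat, vol$grid$spacing, vol$grid$affine)
  }
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary mask on a volume grid
#'
#' @param data 3D logical (or 0/1) array.
#' @param grid the [lge_volume()] whose geometry the mask lives on; the mask
#'   must have the same dimensions.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, grid) {
  if (!inherits(grid, "lge_volume")) stop("grid must be an lge_volume")
  if (!all(dim(data) == dim(grid$data)))
    stop("mask dimensions ", paste(dim(data), collapse = "x"),
         " do not match grid ", paste(dim(grid$data), collapse = "x"))
  structure(list(data = array(as.logical(data), dim = dim(data)), grid = grid),
            class = "binary_mask")
}

#' Read a binary mask from NIfTI
#'
#' @param path NIfTI file; voxels > 0.5 are TRUE.
#' @param grid optional [lge_volume()] to attach; defaults to the geometry
#'   read from the file itself.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, grid = NULL) {
  v <- read_volume(path)
  if (is.null(grid)) grid <- v
  binary_mask(v$data > 0.5, grid)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " set (", signif(100 * mean(x$data), 3), "%)\n", sep = "")
  invisible(x)
}

#' Plot a short-axis slice of a volume
#'
#' @param x an [lge_volume()].
#' @param slice 0-based slice index (third axis); default mid-volume.
#' @param mask optional [binary_mask()] drawn as a contour overlay.
#' @param ... passed to [graphics::image()].
#' @export
plot.lge_volume <- function(x, slice = NULL, mask = NULL, ...) {
  d <- dim(x$data)
  if (is.null(slice)) slice <- (d[3] - 1) %/% 2
  sl <- x$data[, , slice + 1]
  graphics::image(seq_len(d[1]), seq_len(d[2]), sl,
                  col = grDevices::gray.colors(128, 0, 1),
                  xlab = "i", ylab = "j",
                  main = paste0("slice k = ", slice), ...)
  if (!is.null(mask))
    graphics::contour(seq_len(d[1]), seq_len(d[2]),
                      mask$data[, , slice + 1] * 1, levels = 0.5,
                      add = TRUE, drawlabels = FALSE, col = "yellow")
  invisible(x)
}
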