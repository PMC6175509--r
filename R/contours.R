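SURFACE_LABELS <- c("lv_endo", "lv_epi", "rv_endo", "rv_epi")

#' Per-slice anatomical contours
#'
#' An ordered collection of 2D polygons, one per (surface, slice) pair.
#' Each record holds the surface label (`lv_endo`, `lv_epi`, `rv_endo`,
#' `rv_epi`), the 0-based slice index, an ordered n x 2 matrix of in-plane
#' points in mm, and optionally the world z position of the slice plane.
#'
#' @param records list of records, each `list(surface=, slice=, points=,
#'   z=)`; `z` may be omitted when a reference grid will supply it.
#' @param validate check polygon size and simplicity (default TRUE).
#' @return An object of class `contour_set`.
#' @export
contour_set <- function(records, validate = TRUE) {
  for (r in seq_along(records)) {
    rec <- records[[r]]
    if (is.null(rec$surface) || is.na(rec$surface) ||
        !rec$surface %in% SURFACE_LABELS)
      stop("record ", r, ": missing or unknown surface label ",
           "(expected one of ", paste(SURFACE_LABELS, collapse = ", "), ")")
    if (is.null(rec$slice) || !is.finite(rec$slice))
      stop("record ", r, ": missing slice index")
    pts <- as.matrix(rec$points)
    if (ncol(pts) != 2L || nrow(pts) < 3L)
      stop("record ", r, ": polygon must have >= 3 two-dimensional points")
    if (validate && !is_simple_polygon(pts))
      stop("record ", r, ": polygon is self-intersecting")
    records[[r]]$points <- pts
    records[[r]]$slice <- as.integer(rec$slice)
  }
  structure(list(records = records), class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  surf <- vapply(x$records, function(r) r$surface, "")
  cat("<contour_set> ", length(x$records), " contours over ",
      length(unique(vapply(x$records, function(r) r$slice, 0L))),
      " slices\n", sep = "")
  print(table(surface = surf))
  invisible(x)
}

#' @export
length.contour_set <- function(x) length(x$records)

# Segment-intersection test for polygon simplicity (shared endpoints of
# neighbouring edges are allowed).
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    j <- setdiff((i + 2):n, if (i == 1) n else integer())
    if (!length(j)) next
    if (any(segments_intersect(p1[i, ], p2[i, ],
                               p1[j, , drop = FALSE], p2[j, , drop = FALSE])))
      return(FALSE)
  }
  TRUE
}

segments_intersect <- function(a1, a2, b1, b2) {
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a1[1], a1[2])
  d2 <- cross(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a2[1], a2[2])
  d3 <- cross(a1[1], a1[2], a2[1], a2[2], b1[, 1], b1[, 2])
  d4 <- cross(a1[1], a1[2], a2[1], a2[2], b2[, 1], b2[, 2])
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
   ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Signed polygon area (positive for counter-clockwise order)
#'
#' @param pts n x 2 matrix of polygon vertices.
#' @return Signed area in mm^2.
#' @export
polygon_signed_area <- function(pts) {
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  xn <- x[c(2:n, 1)]; yn <- y[c(2:n, 1)]
  sum(x * yn - xn * y) / 2
}

#' Write contours to JSON or CSV
#'
#' JSON schema: an array of objects `{surface, slice, z, points: [[x, y],
#' ...]}` with coordinates in mm.  CSV schema: columns
#' `surface, slice, z, x, y`, points grouped by (surface, slice) in row
#' order.
#'
#' @param contours a [contour_set()].
#' @param path output path; format chosen by extension (.json or .csv).
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  stopifnot(inherits(contours, "contour_set"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- lapply(contours$records, function(r) {
      out <- list(surface = jsonlite::unbox(r$surface),
                  slice = jsonlite::unbox(r$slice),
                  points = unname(r$points))
      if (!is.null(r$z)) out$z <- jsonlite::unbox(r$z)
      out
    })
    writeLines(jsonlite::toJSON(recs, digits = I(17)), path)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- do.call(rbind, lapply(contours$records, function(r) {
      data.frame(surface = r$surface, slice = r$slice,
                 z = if (is.null(r$z)) NA_real_ else r$z,
                 x = r$points[, 1], y = r$points[, 2])
    }))
    utils::write.csv(rows, path, row.names = FALSE)
  } else stop("unsupported contour format (use .json or .csv): ", path)
  invisible(path)
}

#' Read contours from JSON or CSV
#'
#' @param path file written by [write_contours()] (or following its schema).
#' @return A [contour_set()].
#' @export
read_contours <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                               simplifyMatrix = TRUE)
    recs <- lapply(recs, function(r) {
      pts <- r$points
      if (is.list(pts)) pts <- do.call(rbind, pts)
      list(surface = r$surface, slice = r$slice, points = pts, z = r$z)
    })
    contour_set(recs)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    rows <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("surface", "slice", "x", "y")
    if (!all(need %in% names(rows)))
      stop("contour CSV must have columns surface, slice, x, y")
    key <- paste(rows$surface, rows$slice, sep = "\r")
    recs <- lapply(unique(key), function(k) {
      sub <- rows[key == k, , drop = FALSE]
      z <- if ("z" %in% names(sub) && all(is.finite(sub$z))) sub$z[1] else NULL
      list(surface = sub$surface[1], slice = sub$slice[1],
           points = cbind(sub$x, sub$y), z = z)
    })
    contour_set(recs)
  } else stop("unsupported contour format (use .json or .csv): ", path)
}

# world z of a 0-based slice index k under an axis-aligned affine
slice_world_z <- function(grid, k) {
  p <- cbind(0, 0, as.numeric(k), 1) %*% t(grid$affine)
  p[, 3]
}

# records of one surface, each with a usable z (from record or grid)
surface_records <- function(contours, surface_label, grid = NULL) {
  recs <- Filter(function(r) r$surface == surface_label, contours$records)
  if (!length(recs)) stop("no contours with surface label '", surface_label, "'")
  lapply(recs, function(r) {
    if (is.null(r$z)) {
      if (is.null(grid))
        stop("contour records carry no z and no grid was supplied")
      r$z <- slice_world_z(grid, r$slice)
    }
    r
  })
}
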