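# Independent brute-force oracles used to check the implementation.

# Boundary enumeration of a voxel set: exposed unit squares (voxel faces
# whose 6-neighbour is false/outside) and the unique lattice corners they
# touch.  Returns counts comparable to the deduplicated cube mesh.
bf_boundary_counts <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- arr
  idx <- which(pad, arr.ind = TRUE)
  corners <- NULL
  n_squares <- 0L
  shifts <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
  for (s in seq_len(6)) {
    nb <- sweep(idx, 2, shifts[s, ], "+")
    exposed <- !pad[nb]
    if (!any(exposed)) next
    vx <- idx[exposed, , drop = FALSE] - 2L  # 0-based voxel index
    n_squares <- n_squares + nrow(vx)
    ax <- which(shifts[s, ] != 0)
    off <- if (shifts[s, ax] > 0) 1L else 0L
    others <- setdiff(1:3, ax)
    for (da in 0:1) for (db in 0:1) {
      c0 <- vx
      c0[, ax] <- c0[, ax] + off
      c0[, others[1]] <- c0[, others[1]] + da
      c0[, others[2]] <- c0[, others[2]] + db
      corners <- rbind(corners, c0)
    }
  }
  list(squares = n_squares,
       vertices = nrow(unique(corners)),
       triangles = 2L * n_squares)
}

# exposed-face count via direct 6-neighbour scan (vectorised differently)
bf_exposed_faces <- function(arr) {
  d <- dim(arr)
  pad <- array(FALSE, d + 2L)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- arr
  total <- 0L
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    i <- 1 + seq_len(d[1]) + s[1]
    j <- 1 + seq_len(d[2]) + s[2]
    k <- 1 + seq_len(d[3]) + s[3]
    total <- total + sum(arr & !pad[i, j, k])
  }
  total
}

# per-voxel FWHM loop, deliberately naive
bf_fwhm_scar <- function(vol_data, myo_data) {
  ref <- -Inf
  for (i in which(myo_data)) ref <- max(ref, vol_data[i])
  thr <- 0.5 * ref
  out <- array(FALSE, dim(vol_data))
  for (i in which(myo_data)) out[i] <- vol_data[i] > thr
  list(threshold = thr, scar = out)
}

# grid binning oracle for clustering decimation (different code path)
bf_decimate <- function(points, cell) {
  lo <- apply(points, 2, min)
  key <- apply(floor(sweep(points, 2, lo) / cell), 1, paste, collapse = "/")
  out <- t(sapply(split(seq_len(nrow(points)), factor(key, unique(key))),
                  function(i) colMeans(points[i, , drop = FALSE])))
  dimnames(out) <- NULL
  out
}

# crossing-number point-in-polygon, written independently of the C++ kernel
bf_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

# 2D point-to-ellipse distance via a dense polyline (axisymmetric oracle)
bf_ellipse_polyline <- function(a, c, n = 4000) {
  t <- seq(0, pi, length.out = n)  # rho >= 0 half
  cbind(a * sin(t), c * cos(t))
}

bf_dist_to_polyline <- function(pts, line) {
  # min distance from each 2D point to the polyline's vertices (dense enough
  # that segment interpolation is unnecessary)
  out <- numeric(nrow(pts))
  chunk <- 2000L
  for (s in seq(1, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    d2 <- outer(pts[s:e, 1], line[, 1], "-")^2 +
          outer(pts[s:e, 2], line[, 2], "-")^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Independent truth integrator for an axisymmetric phantom: integrates the
# shell in cylindrical (rho, z) with azimuthal sector weights; transmural
# depth from polyline distances to the generating ellipses.
bf_truth_fractions <- function(spec, h = 0.15) {
  stopifnot(abs(spec$lv_endo_radii[1] - spec$lv_endo_radii[2]) < 1e-9,
            abs(spec$lv_epi_radii[1] - spec$lv_epi_radii[2]) < 1e-9)
  ae <- spec$lv_endo_radii[1]; ce <- spec$lv_endo_radii[3]
  ap <- spec$lv_epi_radii[1]; cp <- spec$lv_epi_radii[3]
  zb <- spec$base_fraction * cp
  rho <- seq(h / 2, ap, by = h)
  z <- seq(-cp + h / 2, zb, by = h)
  g <- expand.grid(rho = rho, z = z)
  m_endo <- (g$rho / ae)^2 + (g$z / ce)^2
  m_epi <- (g$rho / ap)^2 + (g$z / cp)^2
  myo <- m_endo >= 1 & m_epi <= 1
  w <- g$rho[myo]  # cylindrical volume weight
  gm <- as.matrix(g[myo, ])
  de <- bf_dist_to_polyline(gm, bf_ellipse_polyline(ae, ce, 6000))
  dp <- bf_dist_to_polyline(gm, bf_ellipse_polyline(ap, cp, 6000))
  depth <- de / (de + dp)
  vol_myo <- sum(w) * 2 * pi
  scar_w <- 0; scar_endo_w <- 0
  for (blob in spec$scar) {
    frac <- min(blob$extent_deg, 360) / 360
    zn <- gm[, 2] / cp
    sel <- depth >= max(blob$depth_range[1], 0) &
           depth <= min(blob$depth_range[2], 1)
    if (!is.null(blob$axial_range))
      sel <- sel & zn >= blob$axial_range[1] & zn <= blob$axial_range[2]
    scar_w <- scar_w + sum(w[sel]) * 2 * pi * frac
    scar_endo_w <- scar_endo_w + sum(w[sel & depth < 1 / 3]) * 2 * pi * frac
  }
  list(scar_volume_fraction = scar_w / vol_myo,
       endocardial_scar_fraction = if (scar_w > 0) scar_endo_w / scar_w else 0,
       surface_scar_area_fraction =
         sum(vapply(spec$scar, function(b)
           if (max(b$depth_range[1], 0) < 1 / 3)
             min(b$extent_deg, 360) / 360 else 0, 0)))
}
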