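#' Scar blob specification for the phantom
#'
#' A scar blob occupies an azimuthal sector of the left-ventricular shell and
#' a transmural depth band anchored (by default) at the endocardium, so its
#' transmural extent is exact by construction.
#'
#' @param center_deg azimuth of the blob centre, degrees.
#' @param extent_deg angular extent of the sector, degrees in (0, 360].
#' @param transmurality transmural extent fraction in (0, 1]; the blob spans
#'   depths `[0, transmurality]` unless `depth_range` overrides it.
#' @param depth_range optional explicit depth band `c(d0, d1)` (used e.g. for
#'   mid-/subepicardial-only scar with subendocardial sparing).
#' @param axial_range optional normalised axial band `c(z0, z1)` in units of
#'   the epicardial long semi-axis (apex = -1, base plane at
#'   `base_fraction`); `NULL` means the full contoured extent.
#' @return An object of class `scar_blob`.
#' @export
scar_blob <- function(center_deg = 110, extent_deg = 75, transmurality = 0.7,
                      depth_range = NULL, axial_range = NULL) {
  if (is.null(depth_range)) depth_range <- c(0, transmurality)
  stopifnot(extent_deg > 0, extent_deg <= 360,
            transmurality > 0, transmurality <= 1,
            length(depth_range) == 2, depth_range[1] < depth_range[2])
  structure(list(center_deg = center_deg, extent_deg = extent_deg,
                 transmurality = transmurality,
                 depth_range = as.numeric(depth_range),
                 axial_range = axial_range),
            class = "scar_blob")
}

#' Phantom specification
#'
#' Describes a synthetic short-axis LGE acquisition of an ellipsoidal-shell
#' left ventricle (optionally with a displaced thin-shell right ventricle),
#' a set of bright scar blobs, and an additive-Gaussian intensity model.
#' Defaults emulate an in-vivo acquisition: 1 mm isotropic voxels, remote
#' myocardium mean 30, scar mean 100, noise SD 2, background (blood pool and
#' air) at half the remote mean.
#'
#' @param lv_endo_radii,lv_epi_radii ellipsoid semi-axes (a, b, c) in mm;
#'   endo must be strictly inside epi.
#' @param spacing voxel spacing (dx, dy, dz) in mm.
#' @param base_fraction basal truncation plane at
#'   `z = base_fraction * lv_epi_radii[3]`.
#' @param margin_mm in-plane/axial padding of the field of view.
#' @param scar list of [scar_blob()]s (possibly empty).
#' @param mu_remote,mu_scar,sigma_noise intensity model (arbitrary units);
#'   `mu_scar > mu_remote`, `sigma_noise >= 0`.
#' @param rv_enabled add a displaced thin-shell right ventricle (rendered and
#'   contoured, excluded from scar quantification).
#' @param n_contour_points polygon size per contour (>= 32).
#' @param seed integer RNG seed; the phantom is deterministic given the seed
#'   and the geometry (masks) is noise- and seed-independent.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lv_endo_radii = c(17, 17, 28),
                         lv_epi_radii = c(26, 26, 38),
                         spacing = c(1, 1, 1),
                         base_fraction = 0.5,
                         margin_mm = 4,
                         scar = list(scar_blob()),
                         mu_remote = 30, mu_scar = 100, sigma_noise = 2,
                         rv_enabled = FALSE,
                         n_contour_points = 128,
                         seed = 1L) {
  lv_endo_radii <- as.numeric(lv_endo_radii); lv_epi_radii <- as.numeric(lv_epi_radii)
  if (!all(lv_endo_radii < lv_epi_radii))
    stop("lv_endo_radii must be componentwise smaller than lv_epi_radii")
  if (!(mu_scar > mu_remote)) stop("mu_scar must exceed mu_remote")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  if (n_contour_points < 32) stop("n_contour_points must be >= 32")
  if (inherits(scar, "scar_blob")) scar <- list(scar)
  structure(list(lv_endo_radii = lv_endo_radii, lv_epi_radii = lv_epi_radii,
                 spacing = as.numeric(spacing),
                 base_fraction = base_fraction, margin_mm = margin_mm,
                 scar = scar, mu_remote = mu_remote, mu_scar = mu_scar,
                 sigma_noise = sigma_noise, rv_enabled = rv_enabled,
                 n_contour_points = as.integer(n_contour_points),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_base_z <- function(spec) spec$base_fraction * spec$lv_epi_radii[3]

# Unsigned Euclidean distance from points to an origin-centred axis-aligned
# ellipsoid surface, by bisection on the KKT parameter of the closest-point
# problem (vectorised over points).
ellipsoid_surface_distance <- function(points, radii) {
  x <- abs(matrix(as.numeric(points), ncol = 3))
  x[x < 1e-9] <- 1e-9
  a2 <- radii^2
  f <- function(t) {
    (a2[1] * x[, 1] / (a2[1] + t))^2 / a2[1] +
    (a2[2] * x[, 2] / (a2[2] + t))^2 / a2[2] +
    (a2[3] * x[, 3] / (a2[3] + t))^2 / a2[3] - 1
  }
  hi <- sqrt((radii[1] * x[, 1])^2 + (radii[2] * x[, 2])^2 +
             (radii[3] * x[, 3])^2)
  lo <- rep(-min(a2) + 1e-9, nrow(x))
  inside_start <- f(0) < 0
  hi[inside_start] <- 0
  lo[!inside_start] <- 0
  for (it in 1:48) {
    mid <- (lo + hi) / 2
    neg <- f(mid) < 0
    hi[neg] <- mid[neg]
    lo[!neg] <- mid[!neg]
  }
  t <- (lo + hi) / 2
  y1 <- a2[1] * x[, 1] / (a2[1] + t)
  y2 <- a2[2] * x[, 2] / (a2[2] + t)
  y3 <- a2[3] * x[, 3] / (a2[3] + t)
  sqrt((x[, 1] - y1)^2 + (x[, 2] - y2)^2 + (x[, 3] - y3)^2)
}

# normalised ellipsoidal radius: < 1 inside, 1 on the surface
ellipsoid_m <- function(points, radii) {
  p <- matrix(as.numeric(points), ncol = 3)
  sqrt((p[, 1] / radii[1])^2 + (p[, 2] / radii[2])^2 + (p[, 3] / radii[3])^2)
}

# Analytic transmural depth: d_endo / (d_endo + d_epi) with exact distances
# to the continuous endo-/epicardial ellipsoids.
phantom_depth <- function(points, spec) {
  de <- ellipsoid_surface_distance(points, spec$lv_endo_radii)
  dp <- ellipsoid_surface_distance(points, spec$lv_epi_radii)
  de / (de + dp)
}

phantom_in_myocardium <- function(points, spec) {
  p <- matrix(as.numeric(points), ncol = 3)
  ellipsoid_m(p, spec$lv_endo_radii) >= 1 &
    ellipsoid_m(p, spec$lv_epi_radii) <= 1 &
    p[, 3] <= phantom_base_z(spec)
}

blob_sector <- function(points, spec, blob) {
  p <- matrix(as.numeric(points), ncol = 3)
  theta <- atan2(p[, 2] / spec$lv_epi_radii[2], p[, 1] / spec$lv_epi_radii[1])
  dtheta <- (theta - blob$center_deg * pi / 180) %% (2 * pi)
  dtheta <- pmin(dtheta, 2 * pi - dtheta)
  ok <- dtheta <= blob$extent_deg * pi / 180 / 2
  if (!is.null(blob$axial_range)) {
    zn <- p[, 3] / spec$lv_epi_radii[3]
    ok <- ok & zn >= blob$axial_range[1] & zn <= blob$axial_range[2]
  }
  ok
}

# scar membership; the (costly) transmural depth is evaluated only for
# myocardial points inside some blob's angular sector
phantom_in_scar <- function(points, spec, myo = NULL) {
  p <- matrix(as.numeric(points), ncol = 3)
  if (is.null(myo)) myo <- phantom_in_myocardium(p, spec)
  out <- rep(FALSE, nrow(p))
  if (!length(spec$scar) || !any(myo)) return(out)
  pm <- p[myo, , drop = FALSE]
  sectors <- lapply(spec$scar, function(b) blob_sector(pm, spec, b))
  sector_any <- Reduce(`|`, sectors)
  hit <- rep(FALSE, nrow(pm))
  if (any(sector_any)) {
    depth <- rep(NA_real_, nrow(pm))
    depth[sector_any] <- phantom_depth(pm[sector_any, , drop = FALSE], spec)
    for (bi in seq_along(spec$scar)) {
      dr <- pmin(pmax(spec$scar[[bi]]$depth_range, 0), 1)
      sel <- sectors[[bi]]
      hit[sel] <- hit[sel] | (depth[sel] >= dr[1] & depth[sel] <= dr[2])
    }
  }
  out[myo] <- hit
  out
}

phantom_grid <- function(spec) {
  s <- spec$spacing
  half_xy <- spec$lv_epi_radii[1:2] + spec$margin_mm
  nx <- 2L * ceiling(half_xy[1] / s[1]) + 1L
  ny <- 2L * ceiling(half_xy[2] / s[2]) + 1L
  zmin <- -(spec$lv_epi_radii[3] + spec$margin_mm)
  zmax <- phantom_base_z(spec) + spec$margin_mm
  nz <- ceiling((zmax - zmin) / s[3]) + 1L
  origin <- c(-(nx - 1) / 2 * s[1], -(ny - 1) / 2 * s[2], zmin)
  lge_volume(array(0, dim = c(nx, ny, nz)), spacing = s,
             affine = make_affine(s, origin))
}

rv_radii <- function(spec) list(endo = c(13, 17, 27), epi = c(16.5, 20.5, 30),
                                center = c(-(spec$lv_epi_radii[1] + 2), 0, -3))

#' Generate a synthetic LGE phantom with ground truth
#'
#' Builds the voxel volume, per-slice contours, myocardium/scar masks and
#' analytic truth fractions for a [phantom_spec()].  Intensities are
#' `mu_remote` in remote myocardium, `mu_scar` in scar, `mu_remote / 2` in
#' the background/blood pool, plus Gaussian noise.  Masks depend only on the
#' geometry, never on the seed or noise level.
#'
#' @param spec a [phantom_spec()].
#' @param truth_resolution_mm step of the fine-grid numerical integration
#'   used for the continuous-geometry truth fractions.
#' @param truth optional precomputed [phantom_truth_fractions()] result
#'   (the truth depends only on the continuous geometry, not the voxel
#'   spacing, so it can be shared between resolutions).
#' @return An object of class `phantom_truth`: `volume`, `contours`,
#'   `myocardium_mask`, `scar_mask`, the three truth fractions (in \[0, 1\]),
#'   and the generating `spec`.
#' @export
generate_phantom <- function(spec, truth_resolution_mm = 0.35, truth = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  for (blob in spec$scar) {
    if (blob$depth_range[1] < 0 || blob$depth_range[2] > 1)
      warning("scar blob depth range extends outside the myocardium; clipped")
  }
  grid <- phantom_grid(spec)
  d <- dim(grid$data)

  myo <- array(FALSE, d); scar <- array(FALSE, d)
  base <- array(spec$mu_remote / 2, d)
  rv <- if (spec$rv_enabled) rv_radii(spec)
  xs <- voxel_centers(grid, cbind(0:(d[1] - 1), 0, 0))[, 1]
  ys <- voxel_centers(grid, cbind(0, 0:(d[2] - 1), 0))[, 2]
  zs <- voxel_centers(grid, cbind(0, 0, 0:(d[3] - 1)))[, 3]
  xy <- as.matrix(expand.grid(x = xs, y = ys))
  for (k in seq_len(d[3])) {
    p <- cbind(xy, zs[k])
    m <- phantom_in_myocardium(p, spec)
    s <- phantom_in_scar(p, spec, myo = m)
    myo[, , k] <- m
    scar[, , k] <- s
    sl <- base[, , k]
    sl[m] <- spec$mu_remote
    sl[s] <- spec$mu_scar
    if (!is.null(rv)) {
      pr <- sweep(p, 2, rv$center)
      inrv <- ellipsoid_m(pr, rv$endo) >= 1 & ellipsoid_m(pr, rv$epi) <= 1 &
        p[, 3] <= phantom_base_z(spec) &
        ellipsoid_m(p, spec$lv_epi_radii) > 1  # trim septal overlap
      sl[inrv & !m] <- spec$mu_remote
    }
    base[, , k] <- sl
  }

  set.seed(spec$seed)
  vol <- grid
  vol$data <- base + array(rnorm(prod(d), 0, spec$sigma_noise), d)

  if (is.null(truth))
    truth <- phantom_truth_fractions(spec, resolution_mm = truth_resolution_mm)

  structure(list(volume = vol,
                 contours = contours_from_phantom(spec, grid),
                 myocardium_mask = binary_mask(myo, grid),
                 scar_mask = binary_mask(scar, grid),
                 true_scar_volume_fraction = truth$scar_volume_fraction,
                 true_endocardial_scar_fraction = truth$endocardial_scar_fraction,
                 true_surface_scar_area_fraction = truth$surface_scar_area_fraction,
                 spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> volume ", paste(dim(x$volume$data), collapse = " x "),
      " @ ", paste(x$spec$spacing, collapse = "x"), " mm, ",
      length(x$contours$records), " contours\n", sep = "")
  cat(sprintf("  truth: scar %.1f%% of LV | endocardial %.1f%% of scar | surface %.1f%%\n",
              100 * x$true_scar_volume_fraction,
              100 * x$true_endocardial_scar_fraction,
              100 * x$true_surface_scar_area_fraction))
  invisible(x)
}

#' Truth fractions from the continuous phantom geometry
#'
#' Numerically integrates the continuous ellipsoid-shell geometry on a fine
#' grid: scar volume as a fraction of LV myocardium, the subendocardial
#' (depth < 1/3) share of scar, and the endocardial surface area fraction
#' subtended by scar anchored at the endocardium.
#'
#' @param spec a [phantom_spec()].
#' @param resolution_mm integration step in mm.
#' @return `list(scar_volume_fraction, endocardial_scar_fraction,
#'   surface_scar_area_fraction)`, all in \[0, 1\].
#' @export
phantom_truth_fractions <- function(spec, resolution_mm = 0.35) {
  h <- resolution_mm
  a <- spec$lv_epi_radii
  xs <- seq(-a[1], a[1], by = h)
  ys <- seq(-a[2], a[2], by = h)
  zs <- seq(-a[3], min(a[3], phantom_base_z(spec)), by = h)
  xy <- as.matrix(expand.grid(x = xs, y = ys))
  n_myo <- 0; n_scar <- 0; n_scar_endo <- 0
  for (z in zs) {
    p <- cbind(xy, z)
    m <- phantom_in_myocardium(p, spec)
    if (!any(m)) next
    n_myo <- n_myo + sum(m)
    if (length(spec$scar)) {
      s <- phantom_in_scar(p, spec, myo = m)
      n_scar <- n_scar + sum(s)
      if (any(s)) {
        ds <- phantom_depth(p[s, , drop = FALSE], spec)
        n_scar_endo <- n_scar_endo + sum(ds < 1 / 3)
      }
    }
  }
  svf <- if (n_myo > 0) n_scar / n_myo else 0
  esf <- if (n_scar > 0) n_scar_endo / n_scar else 0

  # endocardial surface quadrature in (theta, z)
  ssf <- 0
  endo_blobs <- Filter(function(b) min(pmax(b$depth_range, 0)) < 1 / 3, spec$scar)
  er <- spec$lv_endo_radii
  ntheta <- 720L
  theta <- (seq_len(ntheta) - 0.5) / ntheta * 2 * pi
  zq <- seq(-er[3], min(er[3], phantom_base_z(spec)), length.out = 600L)
  zq <- (zq[-1] + zq[-length(zq)]) / 2
  dz <- diff(range(zq)) / (length(zq) - 1)
  total <- 0; covered <- 0
  for (z in zq) {
    s2 <- 1 - (z / er[3])^2
    if (s2 <= 0) next
    s <- sqrt(s2)
    px <- er[1] * s * cos(theta); py <- er[2] * s * sin(theta)
    # area element |p_theta x p_z| dtheta dz
    dpt <- cbind(-er[1] * s * sin(theta), er[2] * s * cos(theta), 0)
    dsdz <- -z / (er[3]^2 * s)
    dpz <- cbind(er[1] * dsdz * cos(theta), er[2] * dsdz * sin(theta), 1)
    cr <- cbind(dpt[, 2] * dpz[, 3] - dpt[, 3] * dpz[, 2],
                dpt[, 3] * dpz[, 1] - dpt[, 1] * dpz[, 3],
                dpt[, 1] * dpz[, 2] - dpt[, 2] * dpz[, 1])
    w <- sqrt(rowSums(cr^2)) * (2 * pi / ntheta) * dz
    total <- total + sum(w)
    if (length(endo_blobs)) {
      hit <- rep(FALSE, ntheta)
      for (blob in endo_blobs)
        hit <- hit | blob_sector(cbind(px, py, z), spec, blob)
      covered <- covered + sum(w[hit])
    }
  }
  if (total > 0) ssf <- covered / total

  list(scar_volume_fraction = svf, endocardial_scar_fraction = esf,
       surface_scar_area_fraction = ssf)
}

#' Slice contours of the phantom ellipsoids
#'
#' Intersects the endo-/epicardial ellipsoids with each short-axis slice
#' plane of the grid and returns the discretised intersection ellipses as
#' ordered counter-clockwise polygons.  Slices that do not intersect a
#' surface (or lie above the basal plane) emit no contour for it.
#'
#' @param spec a [phantom_spec()].
#' @param grid optional [lge_volume()] supplying slice geometry; defaults to
#'   the phantom's own grid.
#' @return A [contour_set()].
#' @export
contours_from_phantom <- function(spec, grid = NULL) {
  if (is.null(grid)) grid <- phantom_grid(spec)
  d <- dim(grid$data)
  n <- spec$n_contour_points
  theta <- 2 * pi * (seq_len(n) - 1) / n
  zb <- phantom_base_z(spec)
  recs <- list()
  surfaces <- list(lv_endo = list(r = spec$lv_endo_radii, c = c(0, 0, 0)),
                   lv_epi = list(r = spec$lv_epi_radii, c = c(0, 0, 0)))
  if (spec$rv_enabled) {
    rv <- rv_radii(spec)
    surfaces$rv_endo <- list(r = rv$endo, c = rv$center)
    surfaces$rv_epi <- list(r = rv$epi, c = rv$center)
  }
  for (k in 0:(d[3] - 1)) {
    z <- slice_world_z(grid, k)
    if (z > zb + 1e-9) next
    for (lab in names(surfaces)) {
      srf <- surfaces[[lab]]
      zrel <- z - srf$c[3]
      s2 <- 1 - (zrel / srf$r[3])^2
      if (s2 <= 1e-6) next
      s <- sqrt(s2)
      pts <- cbind(srf$c[1] + srf$r[1] * s * cos(theta),
                   srf$c[2] + srf$r[2] * s * sin(theta))
      recs[[length(recs) + 1]] <-
        list(surface = lab, slice = k, points = pts, z = z)
    }
  }
  contour_set(recs, validate = FALSE)
}

#' Angular extent achieving a target scar volume fraction
#'
#' For an axisymmetric phantom (equal in-plane semi-axes) the volume of an
#' azimuthal-sector blob is exactly proportional to its angular extent, so
#' the extent for a target scar volume fraction follows from a single
#' reference integration.
#'
#' @param spec a [phantom_spec()] (its scar list is ignored).
#' @param target_fraction desired scar volume as a fraction of LV myocardium.
#' @param transmurality transmural extent of the blob.
#' @param ... passed to [scar_blob()] (e.g. `center_deg`).
#' @return A [scar_blob()] with the required `extent_deg`, or an error if the
#'   target exceeds what the depth band can hold.
#' @export
blob_for_fraction <- function(spec, target_fraction, transmurality, ...) {
  if (abs(spec$lv_endo_radii[1] - spec$lv_endo_radii[2]) > 1e-9 ||
      abs(spec$lv_epi_radii[1] - spec$lv_epi_radii[2]) > 1e-9)
    stop("blob_for_fraction requires an axisymmetric phantom (a == b)")
  ref <- spec
  ref$scar <- list(scar_blob(extent_deg = 360, transmurality = transmurality, ...))
  full <- phantom_truth_fractions(ref, resolution_mm = 0.5)$scar_volume_fraction
  if (target_fraction > full)
    stop(sprintf(paste0("target fraction %.3f exceeds the maximum %.3f ",
                        "attainable with transmural extent %.2f"),
                 target_fraction, full, transmurality))
  scar_blob(extent_deg = 360 * target_fraction / full,
            transmurality = transmurality, ...)
}
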