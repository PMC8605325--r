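#' Projected object area in square micrometres
#'
#' Pixel count of a 2D (maximum-projection) mask converted to um^2 with the
#' lateral pixel size.
#'
#' @param projected_mask 2D logical matrix.
#' @param spacing A [voxel_spacing()].
#' @return Area (um^2).
#' @export
mn_area <- function(projected_mask, spacing) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  sum(projected_mask) * (spacing$dx_nm / 1000) * (spacing$dy_nm / 1000)
}

#' MN volume and sphere-equivalent surface from lamin-positive voxels
#'
#' The MN volume is the average of the minimum-volume enclosing ellipsoid
#' ("inner") and the convex hull ("outer") of the lamin-positive voxel
#' coordinates; the surface area is derived from that volume as the
#' sphere-equivalent surface `pi^(1/3) (6 V)^(2/3)`.
#'
#' @param points n x 3 matrix of lamin-positive coordinates (um).
#' @param tolerance Ellipsoid fit tolerance.
#' @return List of class `volume_estimate`: `v_ellipsoid_um3`, `v_hull_um3`,
#'   `v_mn_um3`, `surface_um2`.
#' @export
mn_volume_surface <- function(points, tolerance = 1e-6) {
  v_ell <- fit_enclosing_ellipsoid(points, tolerance = tolerance)$volume_um3
  v_hull <- convex_hull_volume(points)
  v <- (v_ell + v_hull) / 2
  structure(list(v_ellipsoid_um3 = v_ell, v_hull_um3 = v_hull,
                 v_mn_um3 = v, surface_um2 = sphere_equivalent_surface(v)),
            class = "volume_estimate")
}

#' Sphere-equivalent surface area of a volume
#'
#' @param volume_um3 Volume (um^3).
#' @return Surface area (um^2) of a sphere with that volume.
#' @export
sphere_equivalent_surface <- function(volume_um3) {
  stopifnot(volume_um3 > 0)
  pi^(1 / 3) * (6 * volume_um3)^(2 / 3)
}

# 1D convolution along the given axis of a 3D array, reflected boundary.
# Implemented as a dense band-matrix product along the permuted first axis.
.conv_matrix <- function(len, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  idx <- seq_len(len)
  K <- matrix(0, len, len)
  reflect <- function(j) {
    if (len == 1L) return(rep(1L, length(j)))
    # symmetric extension has period 2*len - 2
    m <- (j - 1L) %% (2L * len - 2L)
    ifelse(m < len, m + 1L, 2L * len - 1L - m)
  }
  for (k in seq_along(kernel)) {
    j <- reflect(idx + (k - half - 1L))
    K[cbind(idx, j)] <- K[cbind(idx, j)] + kernel[k]
  }
  K
}

.conv1d_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- .conv_matrix(d[axis], kernel) %*% m
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

.gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr 3D array `[z, y, x]`.
#' @param sigma_px Length-3 Gaussian sigma in voxels for (z, y, x); 0 skips
#'   an axis.
#' @return Smoothed array.
#' @export
gaussian_smooth_3d <- function(arr, sigma_px) {
  stopifnot(length(sigma_px) == 3L)
  for (ax in 1:3) {
    if (sigma_px[ax] > 0 && dim(arr)[ax] > 1L)
      arr <- .conv1d_axis(arr, .gaussian_kernel(sigma_px[ax]), ax)
  }
  arr
}

.laplacian_3d <- function(arr) {
  d <- dim(arr)
  lap <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 3L) next
    up <- dn <- arr
    idx_lo <- 1:(d[ax] - 1L); idx_hi <- 2:d[ax]
    if (ax == 1L) { up[idx_lo, , ] <- arr[idx_hi, , ]; dn[idx_hi, , ] <- arr[idx_lo, , ] }
    if (ax == 2L) { up[, idx_lo, ] <- arr[, idx_hi, ]; dn[, idx_hi, ] <- arr[, idx_lo, ] }
    if (ax == 3L) { up[, , idx_lo] <- arr[, , idx_hi]; dn[, , idx_hi] <- arr[, , idx_lo] }
    lap <- lap + up + dn - 2 * arr
  }
  lap
}

#' Scale-matched blob (spot) detection in a 3D channel
#'
#' Laplacian-of-Gaussian detection with lateral sigma
#' `diameter / (2 sqrt(2))` and the axial sigma scaled by the axial/lateral
#' anisotropy, so a focus of the nominal diameter (0.2 um for NPC foci)
#' maximizes the response. Local 26-neighbor maxima above `threshold` are
#' kept and refined to sub-voxel positions by a per-axis quadratic fit.
#' Foci closer than the diameter merge into one detection, as with any
#' scale-matched detector.
#'
#' @param channel 3D array `[z, y, x]`.
#' @param spacing A [voxel_spacing()].
#' @param diameter_um Nominal spot diameter (default 0.2 um).
#' @param threshold Response threshold (>= 0). The reference analysis
#'   adjusted this per image; `NA` applies `0.2 * max(response)` and flags
#'   the result as auto-thresholded.
#' @param mask Optional logical array restricting detections.
#' @return Object of class `spot_set`: `coordinates_um` (n x 3, (z, y, x)
#'   um), `count`, `threshold`, `diameter_um`, `auto_threshold`.
#' @export
detect_spots <- function(channel, spacing, diameter_um = 0.2, threshold = NA,
                         mask = NULL) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  d <- dim(channel)
  sigma_um <- diameter_um / (2 * sqrt(2))
  s_xy_px <- sigma_um * 1000 / spacing$dx_nm
  # same physical sigma axially, rescaled by the grid anisotropy dz/dx
  s_z_px <- s_xy_px * spacing$dx_nm / spacing$dz_nm
  sm <- gaussian_smooth_3d(channel, c(s_z_px, s_xy_px, s_xy_px))
  resp <- -s_xy_px^2 * .laplacian_3d(sm)
  resp[resp < 0] <- 0
  auto <- is.na(threshold)
  if (auto) threshold <- 0.2 * max(resp)
  if (threshold < 0) stop("threshold must be >= 0")

  coords <- NULL
  if (max(resp) > 0 && threshold <= max(resp)) {
    # vectorized 26-neighborhood maximum via shifts
    nbmax <- array(-Inf, d)
    for (dz0 in -1:1) for (dy0 in -1:1) for (dx0 in -1:1) {
      if (dz0 == 0 && dy0 == 0 && dx0 == 0) next
      zs <- max(1, 1 + dz0):min(d[1], d[1] + dz0)
      ys <- max(1, 1 + dy0):min(d[2], d[2] + dy0)
      xs <- max(1, 1 + dx0):min(d[3], d[3] + dx0)
      zt <- zs - dz0; yt <- ys - dy0; xt <- xs - dx0
      nbmax[zt, yt, xt] <- pmax(nbmax[zt, yt, xt], resp[zs, ys, xs])
    }
    sel <- resp >= threshold & resp > 0 & resp >= nbmax
    if (!is.null(mask)) sel <- sel & mask
    cand <- which(sel, arr.ind = TRUE)
    # greedy radius suppression: keep the strongest maximum within one spot
    # diameter (two foci closer than the diameter merge, as for any
    # scale-matched detector)
    if (nrow(cand) > 1L) {
      ord <- order(-resp[cand])
      cand <- cand[ord, , drop = FALSE]
      r_lat <- max(1, diameter_um * 1000 / spacing$dx_nm)
      r_ax <- max(1, diameter_um * 1000 / spacing$dz_nm)
      taken <- rep(TRUE, nrow(cand))
      for (i in seq_len(nrow(cand))) {
        if (!taken[i]) next
        if (i < nrow(cand)) {
          later <- (i + 1):nrow(cand)
          close_by <- ((cand[later, 2] - cand[i, 2])^2 +
                         (cand[later, 3] - cand[i, 3])^2) / r_lat^2 +
            (cand[later, 1] - cand[i, 1])^2 / r_ax^2 < 1
          taken[later][close_by] <- FALSE
        }
      }
      cand <- cand[taken, , drop = FALSE]
    }
    if (nrow(cand)) {
      sub <- function(v1, v2, v3) {
        den <- v1 - 2 * v2 + v3
        if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (v1 - v3) / den))
      }
      coords <- t(apply(cand, 1, function(ix) {
        z <- ix[1]; y <- ix[2]; x <- ix[3]
        dz0 <- if (z > 1 && z < d[1]) sub(resp[z - 1, y, x], resp[z, y, x], resp[z + 1, y, x]) else 0
        dy0 <- if (y > 1 && y < d[2]) sub(resp[z, y - 1, x], resp[z, y, x], resp[z, y + 1, x]) else 0
        dx0 <- if (x > 1 && x < d[3]) sub(resp[z, y, x - 1], resp[z, y, x], resp[z, y, x + 1]) else 0
        c((z - 1 + dz0) * spacing$dz_nm, (y - 1 + dy0) * spacing$dy_nm,
          (x - 1 + dx0) * spacing$dx_nm) / 1000
      }))
    }
  }
  if (is.null(coords)) coords <- matrix(numeric(0), ncol = 3)
  colnames(coords) <- c("z_um", "y_um", "x_um")
  structure(list(coordinates_um = coords, count = nrow(coords),
                 threshold = threshold, diameter_um = diameter_um,
                 auto_threshold = auto),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spot(s), diameter %.3g um, threshold %.4g%s\n",
              x$count, x$diameter_um, x$threshold,
              if (x$auto_threshold) " (auto)" else ""))
  invisible(x)
}

#' Spot density and normalization to a reference compartment
#'
#' Focus count per unit surface, optionally normalized to the density of the
#' corresponding nucleus (the published NPC readout).
#'
#' @param spots A [detect_spots()] result (or an integer count).
#' @param surface_um2 Surface area (um^2) of the compartment.
#' @param reference_density Optional reference (nucleus) density (um^-2).
#' @return List: `density_um2`, and `normalized` when a reference is given.
#' @export
spot_density <- function(spots, surface_um2, reference_density = NULL) {
  stopifnot(surface_um2 > 0)
  count <- if (inherits(spots, "spot_set")) spots$count else as.numeric(spots)
  out <- list(density_um2 = count / surface_um2)
  if (!is.null(reference_density)) {
    if (reference_density == 0) stop("reference density is zero")
    out$normalized <- out$density_um2 / reference_density
  }
  out
}
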