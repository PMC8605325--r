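#' Local-contrast normalization of a shell channel
#'
#' Divides each plane by a heavily smoothed copy of itself plus a floor
#' (`floor_frac` of the smoothed maximum). A curved shell imaged in 3D is
#' strongly non-stationary — the tangential rim is many times brighter than
#' the face-on pole — and this flat-fielding puts meshwork ridges (and gap
#' interiors) on a comparable intensity scale everywhere, so that a single
#' per-MN threshold or intensity ratio is meaningful.
#'
#' @param channel 3D array `[z, y, x]`.
#' @param spacing A [voxel_spacing()].
#' @param scale_nm Ridge-filter scale; the smoothing length is 8x this.
#' @param floor_frac Additive floor as a fraction of the smoothed maximum
#'   (damps noise amplification in dark regions).
#' @param footprint Optional 2D mask; the floor reference is taken inside it
#'   so that unrelated bright structure elsewhere in the field (e.g. the
#'   neighbouring nucleus) cannot change the MN's normalization.
#' @return Normalized 3D array.
#' @export
normalize_shell_contrast <- function(channel, spacing, scale_nm = 60,
                                     floor_frac = 0.2, footprint = NULL) {
  sig_big <- 8 * scale_nm / spacing$dx_nm
  k2 <- outer(.gaussian_kernel(sig_big), .gaussian_kernel(sig_big))
  d <- dim(channel)
  sms <- array(0, d)
  for (z in seq_len(d[1])) sms[z, , ] <- .filter2_reflect(channel[z, , ], k2)
  ref <- if (is.null(footprint)) sms else
    sms[array(rep(footprint, each = d[1]), d)]
  # one global floor across planes: a per-plane floor would re-amplify
  # noise in planes that contain no shell
  floor_val <- floor_frac * max(ref, 1e-12)
  channel / (sms + floor_val)
}

# Gaussian and derivatives, 1D, unit-integral gaussian
.g0 <- function(x, s) exp(-x^2 / (2 * s^2)) / (sqrt(2 * pi) * s)
.g1 <- function(x, s) -x / s^2 * .g0(x, s)
.g2 <- function(x, s) (x^2 / s^4 - 1 / s^2) * .g0(x, s)

# Second-derivative basis kernels at scale sigma (pixels), for matrices
# indexed [y, x]: Ixx, Ixy, Iyy obtained by convolution with these.
.steerable_basis <- function(sigma) {
  half <- max(2L, ceiling(3 * sigma))
  x <- (-half):half
  g0v <- .g0(x, sigma)
  g1v <- .g1(x, sigma)
  # zero-mean the truncated second derivative so a constant image gives an
  # exactly zero response
  g2v <- .g2(x, sigma)
  g2v <- g2v - mean(g2v)
  list(
    gxx = outer(g0v, g2v),
    gxy = outer(g1v, g1v),
    gyy = outer(g2v, g0v),
    half = half
  )
}

# reflective-padding 2D convolution via EBImage FFT filtering; symmetric
# extension is folded periodically so kernels larger than the plane work
.filter2_reflect <- function(m, kern) {
  h <- (dim(kern)[1] - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) stop("plane smaller than filter support")
  reflect_idx <- function(j, len) {
    mm <- (j - 1L) %% (2L * len - 2L)
    ifelse(mm < len, mm + 1L, 2L * len - 1L - mm)
  }
  ridx <- reflect_idx((1L - h):(nr + h), nr)
  cidx <- reflect_idx((1L - h):(nc + h), nc)
  mp <- m[ridx, cidx]
  out <- EBImage::filter2(mp, kern, boundary = "circular")
  out[(h + 1):(h + nr), (h + 1):(h + nc)]
}

#' Multi-orientation steerable ridge response of a 3D stack
#'
#' Per z-plane even second-order Gaussian-derivative line filtering: the
#' response at line direction theta is the (negated, clipped at 0) second
#' derivative of the Gaussian-smoothed plane along the normal to theta,
#' scale-normalized by sigma^2. Because the filter is steerable, responses
#' at all orientations derive from the three basis convolutions Ixx, Ixy,
#' Iyy; the per-voxel maximum over `n_orientations` equally spaced
#' directions and the maximizing direction are returned.
#'
#' @param channel 3D array `[z, y, x]` (one fluorescence channel).
#' @param spacing A [voxel_spacing()].
#' @param scale_nm Filter scale (Gaussian sigma, nm); must be >= the lateral
#'   pixel size. Default 60 nm, matched to lamin filament bundle width at
#'   STED resolution.
#' @param n_orientations Number of line directions in `[0, pi)` (>= 4).
#' @return Object of class `ridge_response`: `response` (3D, >= 0),
#'   `orientation` (3D, line direction in `[0, pi)`, `NA` where the
#'   response is 0), `scale_nm`, `border_px` (half filter support; voxels
#'   closer to the lateral border are boundary-flagged).
#' @export
steerable_ridge_response <- function(channel, spacing, scale_nm = 60,
                                     n_orientations = 12L) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  if (scale_nm < spacing$dx_nm)
    stop("scale_nm must be at least the lateral pixel size")
  if (n_orientations < 4L) stop("n_orientations must be >= 4")
  sigma <- scale_nm / spacing$dx_nm
  basis <- .steerable_basis(sigma)
  d <- dim(channel)
  thetas <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  resp <- array(0, d)
  orient <- array(NA_real_, d)
  for (z in seq_len(d[1])) {
    pl <- channel[z, , ]
    ixx <- .filter2_reflect(pl, basis$gxx)
    ixy <- .filter2_reflect(pl, basis$gxy)
    iyy <- .filter2_reflect(pl, basis$gyy)
    best <- matrix(-Inf, d[2], d[3])
    besttheta <- matrix(0, d[2], d[3])
    for (th in thetas) {
      # normal to the line direction
      nx <- -sin(th); ny <- cos(th)
      dnn <- nx * nx * ixx + 2 * nx * ny * ixy + ny * ny * iyy
      r <- -sigma^2 * dnn
      upd <- r > best
      best[upd] <- r[upd]
      besttheta[upd] <- th
    }
    best[best < 0] <- 0
    # FFT filtering leaves ~1e-15 ripple; clip it so flat regions are
    # exactly zero and NMS cannot promote numerical noise
    clip <- max(1e-9 * max(best), 1e-11 * sigma^2 * max(abs(pl)))
    best[best < clip] <- 0
    resp[z, , ] <- best
    o <- besttheta
    o[best == 0] <- NA_real_
    orient[z, , ] <- o
  }
  structure(list(response = resp, orientation = orient, scale_nm = scale_nm,
                 n_orientations = as.integer(n_orientations),
                 border_px = basis$half),
            class = "ridge_response")
}

.bilinear_sample <- function(m, yq, xq) {
  nr <- nrow(m); nc <- ncol(m)
  y0 <- floor(yq); x0 <- floor(xq)
  fy <- yq - y0; fx <- xq - x0
  ok <- y0 >= 1 & x0 >= 1 & y0 + 1 <= nr & x0 + 1 <= nc
  out <- numeric(length(yq))
  i <- which(ok)
  if (length(i)) {
    v00 <- m[cbind(y0[i], x0[i])]
    v01 <- m[cbind(y0[i], x0[i] + 1)]
    v10 <- m[cbind(y0[i] + 1, x0[i])]
    v11 <- m[cbind(y0[i] + 1, x0[i] + 1)]
    out[i] <- v00 * (1 - fy[i]) * (1 - fx[i]) + v01 * (1 - fy[i]) * fx[i] +
      v10 * fy[i] * (1 - fx[i]) + v11 * fy[i] * fx[i]
  }
  out
}

#' Non-maximum suppression of a ridge response
#'
#' A voxel survives iff its response is >= both bilinear samples taken one
#' pixel away along the in-plane normal to its ridge orientation, leaving a
#' one-pixel-thick centerline across each ridge.
#'
#' @param resp A [steerable_ridge_response()] result.
#' @return Logical 3D array of centerline voxels.
#' @export
non_maximum_suppression <- function(resp) {
  stopifnot(inherits(resp, "ridge_response"))
  d <- dim(resp$response)
  keep <- array(FALSE, d)
  for (z in seq_len(d[1])) {
    r <- resp$response[z, , ]
    o <- resp$orientation[z, , ]
    idx <- which(r > 0, arr.ind = TRUE)
    if (!nrow(idx)) next
    th <- o[idx]
    nx <- -sin(th); ny <- cos(th)
    yq <- idx[, 1]; xq <- idx[, 2]
    r0 <- r[idx]
    rp <- .bilinear_sample(r, yq + ny, xq + nx)
    rm <- .bilinear_sample(r, yq - ny, xq - nx)
    k <- matrix(FALSE, d[2], d[3])
    k[idx] <- r0 >= rp & r0 >= rm
    keep[z, , ] <- k
  }
  keep
}

#' Response-weighted segmentation of the lamin meshwork
#'
#' Composition of [steerable_ridge_response()] and
#' [non_maximum_suppression()], retaining NMS survivors whose response
#' exceeds a quantile of the positive NMS responses (computed within the MN
#' footprint when one is given, so the threshold adapts per object). The
#' response magnitudes are carried along as segmentation weights.
#'
#' @param channel 3D lamin channel `[z, y, x]`.
#' @param spacing A [voxel_spacing()].
#' @param params List with `scale_nm`, `n_orientations`,
#'   `response_quantile` (missing entries take the defaults 60, 12, 0.5).
#' @param footprint Optional 2D logical mask restricting the analysis
#'   (applied to every plane).
#' @return Object of class `meshwork_segmentation`: `centerline_mask`
#'   (logical 3D), `response_weights` (3D, response on the mask, 0
#'   elsewhere), `threshold`, `params`, `border_px`.
#' @details With `normalize = TRUE` (default) each plane is divided by a
#'   heavily smoothed copy of itself (plus a floor of 20% of its maximum)
#'   before filtering. A curved shell imaged in 3D is strongly
#'   non-stationary — the tangential rim is many times brighter than the
#'   face-on pole — and this local-contrast normalization puts meshwork
#'   ridges at comparable response levels everywhere so that one quantile
#'   threshold is meaningful across the whole MN.
#' @export
segment_meshwork <- function(channel, spacing, params = list(),
                             footprint = NULL) {
  p <- utils::modifyList(list(scale_nm = 60, n_orientations = 12L,
                              response_quantile = 0.5, normalize = TRUE,
                              gate_frac = 2.5), params)
  raw <- channel
  if (isTRUE(p$normalize))
    channel <- normalize_shell_contrast(channel, spacing, p$scale_nm,
                                        footprint = footprint)
  rr <- steerable_ridge_response(channel, spacing, p$scale_nm,
                                 p$n_orientations)
  nms <- non_maximum_suppression(rr)
  inside <- nms
  if (!is.null(footprint)) {
    if (!sum(footprint)) stop("empty footprint")
    for (z in seq_len(dim(nms)[1])) inside[z, , ] <- nms[z, , ] & footprint
  }
  # the response threshold is the quantile of ALL positive NMS responses in
  # the footprint (gating must not shift it: the weak noise responses are
  # part of the distribution the quantile is defined on)
  vals <- rr$response[inside]
  vals <- vals[vals > 0]
  # signal gate: ridges only count where the raw channel carries signal,
  # otherwise flat-fielding promotes empty-plane noise into centerlines.
  # The gate is gate_frac x the footprint's lower-quartile smoothed
  # intensity (a robust background estimate, since interior voxels dominate
  # the footprint volume); NULL or 0 disables.
  if (!is.null(p$gate_frac) && p$gate_frac > 0) {
    s_px <- p$scale_nm / spacing$dx_nm
    # lateral-only smoothing: axial smoothing would dilute a shell that
    # spans a single plane (the polar cap) below the gate
    sm3 <- gaussian_smooth_3d(raw, c(0, s_px, s_px))
    ref <- if (is.null(footprint)) sm3 else {
      fp3 <- array(rep(footprint, each = dim(raw)[1]), dim(raw))
      sm3[fp3]
    }
    gate <- p$gate_frac * stats::quantile(ref, 0.25, names = FALSE)
    inside <- inside & (sm3 > gate)
  }
  if (p$response_quantile >= 1 || !length(vals)) {
    mask <- array(FALSE, dim(nms))
    thr <- Inf
  } else {
    thr <- stats::quantile(vals, p$response_quantile, names = FALSE)
    mask <- inside & rr$response >= thr
  }
  w <- array(0, dim(mask))
  w[mask] <- rr$response[mask]
  structure(list(centerline_mask = mask, response_weights = w,
                 threshold = thr, params = p, border_px = rr$border_px),
            class = "meshwork_segmentation")
}
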