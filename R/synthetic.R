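# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

#' Specification of one inserted lamina gap
#'
#' @param theta,phi Spherical position of the gap center on the shell
#'   (polar angle from the +z pole, azimuth; radians).
#' @param area_um2 Target gap surface area (> 0).
#' @param residual_fraction Lamin intensity retained inside the gap (0-1;
#'   0 = fully devoid of lamin).
#' @return Object of class `gap_spec`.
#' @export
gap_spec <- function(theta, phi, area_um2, residual_fraction = 0) {
  stopifnot(area_um2 > 0, residual_fraction >= 0, residual_fraction <= 1)
  structure(list(theta = theta, phi = phi, area_um2 = area_um2,
                 residual_fraction = residual_fraction), class = "gap_spec")
}

#' Specification of a synthetic micronucleus stack
#'
#' Defines an oblate-spheroid lamin shell with meshwork texture, optional
#' inserted gaps, a chromatin-filled interior, an H3K27ac level encoding the
#' rupture state, nucleoporin-like surface foci and centromere foci, plus a
#' rectangular "nucleus" region rendered beside the MN as the reference
#' compartment for rupture and rim normalization. Imaging is emulated by an
#' anisotropic Gaussian PSF and Poisson + Gaussian noise at STED-like
#' sampling (20 nm lateral, 150 nm axial).
#'
#' @param semi_axes_um Spheroid semi-axes `(a, b, c)` um with
#'   `a >= b >= c > 0`.
#' @param shell_thickness_um Radial thickness of the lamin band.
#' @param mesh_spacing_um Characteristic meshwork face size (correlation
#'   length of the line-generating random field).
#' @param mesh_line_fraction Fraction of the shell surface covered by mesh
#'   lines.
#' @param gaps List of [gap_spec()]s.
#' @param channels Channels to render (subset of `dna`, `lamin`,
#'   `h3k27ac`, `spots`, `centromere`).
#' @param psf_sigma_nm `(lateral, axial)` Gaussian PSF sigma.
#' @param poisson_scale Photon count at unit intensity (0 = noiseless).
#' @param gaussian_sigma Additive read-noise sd (photon units).
#' @param spacing A [voxel_spacing()] (default 20, 20, 150 nm).
#' @param rupture_state `"intact"` or `"ruptured"`.
#' @param h3k27ac_ratio_ruptured MN/nucleus H3K27ac mean ratio rendered for
#'   ruptured MN (default 0.39, just under the 0.4 call threshold; intact
#'   MN render at 1.0).
#' @param mn_lamin_brightness Shell amplitude relative to the nucleus rim.
#' @param n_spots Number of NPC-like surface foci.
#' @param n_centromeres Number of centromere foci in the interior.
#' @param render_nucleus Include the reference nucleus region.
#' @return Object of class `synthetic_mn_spec`.
#' @export
synthetic_mn_spec <- function(semi_axes_um = c(1.0, 0.95, 0.6),
                              shell_thickness_um = 0.06,
                              mesh_spacing_um = 0.10,
                              mesh_line_fraction = 0.45,
                              gaps = list(),
                              channels = c("dna", "lamin", "h3k27ac",
                                           "spots", "centromere"),
                              psf_sigma_nm = c(25, 120),
                              poisson_scale = 150,
                              gaussian_sigma = 2,
                              spacing = voxel_spacing(20, 20, 150),
                              rupture_state = c("intact", "ruptured"),
                              h3k27ac_ratio_ruptured = 0.39,
                              mn_lamin_brightness = 1,
                              n_spots = 0L,
                              n_centromeres = 1L,
                              render_nucleus = TRUE) {
  rupture_state <- match.arg(rupture_state)
  a <- semi_axes_um
  if (!(a[1] >= a[2] && a[2] >= a[3] && a[3] > 0))
    stop("semi-axes must satisfy a >= b >= c > 0")
  if (length(gaps) && !all(vapply(gaps, inherits, TRUE, "gap_spec")))
    stop("gaps must be a list of gap_spec objects")
  structure(list(semi_axes_um = a, shell_thickness_um = shell_thickness_um,
                 mesh_spacing_um = mesh_spacing_um,
                 mesh_line_fraction = mesh_line_fraction, gaps = gaps,
                 channels = channels, psf_sigma_nm = psf_sigma_nm,
                 poisson_scale = poisson_scale, gaussian_sigma = gaussian_sigma,
                 spacing = spacing, rupture_state = rupture_state,
                 h3k27ac_ratio_ruptured = h3k27ac_ratio_ruptured,
                 mn_lamin_brightness = mn_lamin_brightness,
                 n_spots = as.integer(n_spots),
                 n_centromeres = as.integer(n_centromeres),
                 render_nucleus = render_nucleus),
            class = "synthetic_mn_spec")
}

# approximate ellipsoid surface area (Thomsen/Knud formula, p = 1.6075)
.ellipsoid_surface <- function(a, b, c3) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c3)^p + (b * c3)^p) / 3)^(1 / p)
}

#' Generate a synthetic MN stack with ground truth
#'
#' Deterministic in `(spec, seed)`. The lamin channel renders the spheroid
#' shell band modulated by a meshwork texture (level-set lines of a smooth
#' random field), down-weighted by `residual_fraction` inside each gap
#' footprint, then convolved with the PSF and corrupted by Poisson +
#' Gaussian noise. The DNA channel fills the interior; the H3K27ac level
#' inside the MN encodes the rupture state relative to the rendered nucleus;
#' surface foci of ~0.2 um FWHM populate the spot channel.
#'
#' @param spec A [synthetic_mn_spec()].
#' @param seed Integer seed.
#' @return List: `stack` (an [image_stack()]) and `truth` (list with the
#'   MN footprint and center, per-gap requested/realized areas and projected
#'   footprints with hemisphere assignment, closed-form spheroid volume and
#'   surface, spot and centromere coordinates (um), rupture state, rendered
#'   H3K27ac ratio, the nucleus masks, and the noiseless channels).
#' @export
generate_mn_stack <- function(spec, seed) {
  stopifnot(inherits(spec, "synthetic_mn_spec"))
  sp <- spec$spacing
  dx <- sp$dx_nm / 1000; dy <- sp$dy_nm / 1000; dz <- sp$dz_nm / 1000
  a <- spec$semi_axes_um[1]; b <- spec$semi_axes_um[2]; c3 <- spec$semi_axes_um[3]
  if (2 * c3 / dz < 5) stop("spacing incompatible with semi-axes: fewer than 5 z-planes across the MN")
  surf_total <- .ellipsoid_surface(a, b, c3)
  if (length(spec$gaps) &&
      sum(vapply(spec$gaps, `[[`, 0, "area_um2")) > 0.5 * surf_total)
    stop("gap areas jointly exceed half the shell surface")

  margin_xy <- 0.3; margin_z <- 0.35
  slab_w_um <- if (spec$render_nucleus) 0.5 else 0
  slab_gap_um <- if (spec$render_nucleus) 0.2 else 0
  nx <- ceiling((2 * a + 2 * margin_xy + slab_w_um + slab_gap_um) / dx)
  ny <- ceiling((2 * b + 2 * margin_xy) / dy)
  nz <- max(5L, ceiling((2 * c3 + 2 * margin_z) / dz))
  cx <- slab_w_um + slab_gap_um + margin_xy + a
  cy <- margin_xy + b
  cz <- ((nz - 1) / 2) * dz
  xs <- (seq_len(nx) - 1) * dx - cx
  ys <- (seq_len(ny) - 1) * dy - cy
  zs <- (seq_len(nz) - 1) * dz - cz

  # normalized radius g and approximate signed distance to the shell
  x2 <- (xs / a)^2; y2 <- (ys / b)^2; z2 <- (zs / c3)^2
  g2 <- array(rep(z2, times = ny * nx), c(nz, ny, nx)) +
    array(rep(rep(y2, each = nz), times = nx), c(nz, ny, nx)) +
    array(rep(x2, each = nz * ny), c(nz, ny, nx))
  g <- sqrt(g2)
  gx2 <- array(rep((xs / a^2)^2, each = nz * ny), c(nz, ny, nx))
  gy2 <- array(rep(rep((ys / b^2)^2, each = nz), times = nx), c(nz, ny, nx))
  gz2 <- array(rep((zs / c3^2)^2, times = ny * nx), c(nz, ny, nx))
  gradmag <- sqrt(gx2 + gy2 + gz2) / pmax(g, 1e-9)
  dist_um <- (g - 1) / pmax(gradmag, 1e-9)

  half_th <- spec$shell_thickness_um / 2
  # surface-density rendering: voxel signal scales with the shell area it
  # contains, ~1/cos(tilt) capped by the voxel aspect — this produces the
  # bright equatorial rim every real z-stack of a lamin shell shows
  cos_tilt <- sqrt(gz2) / pmax(sqrt(gx2 + gy2 + gz2), 1e-12)
  sin_tilt <- sqrt(pmax(1 - cos_tilt^2, 0))
  tilt_w <- pmin(1 / pmax(cos_tilt, 1e-3), sp$dz_nm / sp$dx_nm)
  # anti-aliased band: the radial profile is widened by the voxel footprint
  # along the surface normal (dz/2 where face-on, dx/2 where edge-on), so a
  # shell patch between z-samples still deposits signal in the grid instead
  # of vanishing (point-sampling a 60 nm shell on a 150 nm grid aliases)
  w_loc <- sqrt(half_th^2 + (dz / 2 * cos_tilt)^2 + (dx / 2 * sin_tilt)^2)
  band <- exp(-dist_um^2 / (2 * w_loc^2))
  in_band <- abs(dist_um) <= 2.5 * w_loc

  .with_seed(seed, {
    # meshwork texture: level-set lines of a smoothed random field
    noise <- array(stats::rnorm(nz * ny * nx), c(nz, ny, nx))
    s_xy <- spec$mesh_spacing_um / 2 / dx
    s_z <- spec$mesh_spacing_um / 2 / dz
    field <- gaussian_smooth_3d(noise, c(max(s_z, 0.3), s_xy, s_xy))
    w <- stats::quantile(abs(field[in_band]), spec$mesh_line_fraction,
                         names = FALSE)
    lineness <- pmax(1 - (abs(field) / max(w, 1e-9))^2, 0)
    # inter-line veil at 0.75 of line level, calibrated (together with the
    # 0.12 um mesh spacing) so that gap-free shells, measured through the
    # package's own pipeline, reproduce the published normal-lamina bounds:
    # hole areas at most ~0.12 um^2 and intensity ratios bottoming out near
    # (never below) 0.5
    lamin0 <- band * tilt_w * (0.75 + 0.25 * lineness) *
      spec$mn_lamin_brightness

    # gap footprints: geodesic caps around the center direction, applied to
    # the radial projection of each shell voxel
    ghat <- pmax(g, 1e-9)
    px_area <- dx * dy
    gap_rows <- list(); gap_fp <- list()
    if (length(spec$gaps)) {
      sx <- array(rep(xs, each = nz * ny), c(nz, ny, nx)) / ghat
      sy <- array(rep(rep(ys, each = nz), times = nx), c(nz, ny, nx)) / ghat
      sz <- array(rep(zs, times = ny * nx), c(nz, ny, nx)) / ghat
      for (gi in seq_along(spec$gaps)) {
        gsp <- spec$gaps[[gi]]
        pc <- c(a * sin(gsp$theta) * cos(gsp$phi),
                b * sin(gsp$theta) * sin(gsp$phi),
                c3 * cos(gsp$theta))
        r <- sqrt(gsp$area_um2 / pi)
        d2 <- (sx - pc[1])^2 + (sy - pc[2])^2 + (sz - pc[3])^2
        inside <- d2 <= r^2
        # a gap retains diffuse residual lamin, not a dim intact meshwork:
        # replace the texture by a structureless level of the requested
        # fraction of the mean shell brightness
        sel <- inside & in_band
        lamin0[sel] <- (band * tilt_w)[sel] * gsp$residual_fraction * 0.87 *
          spec$mn_lamin_brightness
        hemi <- if (pc[3] <= 0) "bottom" else "top"
        # analytic projected footprint: for each lateral pixel on the
        # ellipse, take the surface point on the gap's hemisphere and test
        # the cap condition (avoids z-grid discretization of the thin band)
        e2 <- outer((ys / b)^2, (xs / a)^2, `+`)
        zs_surf <- c3 * sqrt(pmax(1 - e2, 0)) * sign(pc[3] + 1e-12)
        sxm <- matrix(rep(xs, each = ny), ny, nx)
        sym <- matrix(rep(ys, times = nx), ny, nx)
        d2s <- (sxm - pc[1])^2 + (sym - pc[2])^2 + (zs_surf - pc[3])^2
        fp2 <- e2 <= 1 & d2s <= r^2
        # tilt-corrected surface area of the projected footprint
        nzv <- pmax(abs(zs_surf) / c3^2, 1e-9)
        nvec <- sqrt((sxm / a^2)^2 + (sym / b^2)^2 + (zs_surf / c3^2)^2)
        cosf <- pmax(nzv / pmax(nvec, 1e-12), 0.05)
        realized_surface <- sum(px_area / cosf[fp2])
        gap_rows[[gi]] <- data.frame(
          gap_id = gi, theta = gsp$theta, phi = gsp$phi,
          requested_area_um2 = gsp$area_um2,
          residual_fraction = gsp$residual_fraction,
          hemisphere = hemi,
          realized_area_um2 = realized_surface,
          projected_area_um2 = sum(fp2) * px_area)
        gap_fp[[gi]] <- fp2
      }
    }

    interior <- g <= 1
    dna0 <- pmin(pmax((1 - g) / 0.05, 0), 1)        # soft-edged fill
    ratio <- if (spec$rupture_state == "ruptured")
      spec$h3k27ac_ratio_ruptured else 1.0
    h3k0 <- dna0 * ratio

    nuc3 <- array(FALSE, c(nz, ny, nx))
    lamin_nuc <- array(0, c(nz, ny, nx))
    if (spec$render_nucleus) {
      xin <- xs >= -cx + 0.1 & xs <= -cx + 0.1 + slab_w_um
      yin <- ys >= ys[1] + 0.1 & ys <= ys[ny] - 0.1
      zin <- abs(zs) <= c3
      nuc3 <- outer(outer(zin, yin), xin) > 0
      dim(nuc3) <- c(nz, ny, nx)
      # rim of the slab: within 0.06 um of its boundary
      shiftin <- function(m) {
        s <- m
        s[2:(nz - 1), 2:(ny - 1), 2:(nx - 1)] <-
          m[2:(nz - 1), 2:(ny - 1), 2:(nx - 1)] &
          m[1:(nz - 2), 2:(ny - 1), 2:(nx - 1)] &
          m[3:nz, 2:(ny - 1), 2:(nx - 1)] &
          m[2:(nz - 1), 1:(ny - 2), 2:(nx - 1)] &
          m[2:(nz - 1), 3:ny, 2:(nx - 1)] &
          m[2:(nz - 1), 2:(ny - 1), 1:(nx - 2)] &
          m[2:(nz - 1), 2:(ny - 1), 3:nx]
        s
      }
      ner <- nuc3
      for (k in seq_len(max(1L, round(0.06 / dx)))) ner <- shiftin(ner)
      rim3 <- nuc3 & !ner
      # wall brightness calibrated so that an MN rendered at
      # mn_lamin_brightness = b measures a rim ratio of ~b against this
      # reference (the slab wall and the spheroid rim have different
      # geometry, so the raw surface-density levels are not comparable)
      lamin_nuc[rim3] <- 3.15
      h3k0[nuc3] <- pmax(h3k0[nuc3], 1)
      dna0[nuc3] <- pmax(dna0[nuc3], 1)
    }
    lamin0 <- pmax(lamin0, lamin_nuc)

    spots0 <- array(0, c(nz, ny, nx))
    spot_xyz <- matrix(numeric(0), ncol = 3)
    if (spec$n_spots > 0L) {
      pts <- matrix(numeric(0), ncol = 3)
      tries <- 0L
      while (nrow(pts) < spec$n_spots && tries < 20000L) {
        tries <- tries + 1L
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        p <- c(a * u[1], b * u[2], c3 * u[3])
        if (nrow(pts) == 0L ||
            min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= 0.4)
          pts <- rbind(pts, p)
      }
      if (nrow(pts) < spec$n_spots)
        stop("could not place the requested spots at 0.4 um separation")
      spot_xyz <- pts
      s_lat <- 0.2 / 2.355; s_ax <- 0.22
      for (i in seq_len(nrow(pts))) {
        p <- pts[i, ]
        zi <- which(abs(zs - p[3]) <= 3 * s_ax)
        yi <- which(abs(ys - p[2]) <= 3 * s_lat)
        xi <- which(abs(xs - p[1]) <= 3 * s_lat)
        if (!length(zi) || !length(yi) || !length(xi)) next
        gz <- exp(-(zs[zi] - p[3])^2 / (2 * s_ax^2))
        gy <- exp(-(ys[yi] - p[2])^2 / (2 * s_lat^2))
        gx <- exp(-(xs[xi] - p[1])^2 / (2 * s_lat^2))
        blob <- outer(outer(gz, gy), gx)
        dim(blob) <- c(length(zi), length(yi), length(xi))
        spots0[zi, yi, xi] <- spots0[zi, yi, xi] + blob
      }
    }

    cen0 <- array(0, c(nz, ny, nx))
    cen_xyz <- matrix(numeric(0), ncol = 3)
    if (spec$n_centromeres > 0L) {
      pts <- matrix(numeric(0), ncol = 3)
      while (nrow(pts) < spec$n_centromeres) {
        u <- stats::runif(3, -0.55, 0.55)
        p <- c(a * u[1], b * u[2], c3 * u[3])
        if (nrow(pts) == 0L ||
            min(sqrt(rowSums(sweep(pts, 2, p)^2))) >= 0.45)
          pts <- rbind(pts, p)
      }
      cen_xyz <- pts
      s_lat <- 0.12; s_ax <- 0.25
      for (i in seq_len(nrow(pts))) {
        p <- pts[i, ]
        zi <- which(abs(zs - p[3]) <= 3 * s_ax)
        yi <- which(abs(ys - p[2]) <= 3 * s_lat)
        xi <- which(abs(xs - p[1]) <= 3 * s_lat)
        gz <- exp(-(zs[zi] - p[3])^2 / (2 * s_ax^2))
        gy <- exp(-(ys[yi] - p[2])^2 / (2 * s_lat^2))
        gx <- exp(-(xs[xi] - p[1])^2 / (2 * s_lat^2))
        blob <- outer(outer(gz, gy), gx)
        dim(blob) <- c(length(zi), length(yi), length(xi))
        cen0[zi, yi, xi] <- cen0[zi, yi, xi] + blob
      }
    }

    clean <- list(dna = dna0, lamin = lamin0, h3k27ac = h3k0,
                  spots = spots0, centromere = cen0)
    clean <- clean[intersect(spec$channels, names(clean))]
    s_psf <- c(spec$psf_sigma_nm[2] / sp$dz_nm,
               spec$psf_sigma_nm[1] / sp$dy_nm,
               spec$psf_sigma_nm[1] / sp$dx_nm)
    blurred <- lapply(clean, gaussian_smooth_3d, sigma_px = s_psf)
    noisy <- lapply(blurred, function(ch) {
      if (spec$poisson_scale <= 0) return(ch)
      counts <- array(stats::rpois(length(ch), ch * spec$poisson_scale),
                      dim(ch))
      if (spec$gaussian_sigma > 0)
        counts <- counts + array(stats::rnorm(length(ch),
                                              sd = spec$gaussian_sigma),
                                 dim(ch))
      pmax(counts, 0) / spec$poisson_scale
    })

    stack <- image_stack(noisy, sp,
                         metadata = list(generator = "mnlamina-synthetic",
                                         seed = seed,
                                         rupture_state = spec$rupture_state))
    truth <- list(
      center_um = c(z = cz, y = cy, x = cx),
      semi_axes_um = spec$semi_axes_um,
      volume_um3 = 4 * pi / 3 * a * b * c3,
      surface_um2 = surf_total,
      footprint = apply(interior, c(2, 3), any),
      interior = interior,
      equator_z = which.min(abs(zs)),
      gaps = if (length(gap_rows)) do.call(rbind, gap_rows) else
        data.frame(),
      gap_footprints = gap_fp,
      spot_coords_um = spot_xyz,
      centromere_coords_um = cen_xyz,
      nucleus_mask = nuc3,
      rupture_state = spec$rupture_state,
      h3k27ac_ratio = ratio,
      noiseless = blurred)
    list(stack = stack, truth = truth)
  })
}

#' Draw non-overlapping random gap specifications
#'
#' Places `n` gaps on the shell with centers confined to the well-sampled
#' polar zones (polar angle within `theta_range` of either pole) and
#' pairwise chord separation of at least the sum of cap radii plus
#' `min_sep_um`, so that inserted gaps are distinct objects. Deterministic
#' in `seed`.
#'
#' @param n Number of gaps.
#' @param seed Integer seed.
#' @param semi_axes_um Shell semi-axes (used for the separation test).
#' @param area_range_um2 Gap area range (default 0.15-0.5).
#' @param residual_range Residual-intensity range (default 0-0.2).
#' @param theta_range Polar-angle band (radians from a pole).
#' @param min_sep_um Extra center separation margin.
#' @return List of [gap_spec()]s (length may be < `n` if placement fails).
#' @export
random_gap_specs <- function(n, seed, semi_axes_um = c(1.0, 0.95, 0.6),
                             area_range_um2 = c(0.15, 0.5),
                             residual_range = c(0, 0.2),
                             theta_range = c(0.25, 0.65),
                             min_sep_um = 0.25) {
  if (n == 0L) return(list())
  .with_seed(seed, {
    gaps <- list(); centers <- NULL; tries <- 0L
    while (length(gaps) < n && tries < 1000L) {
      tries <- tries + 1L
      th <- stats::runif(1, theta_range[1], theta_range[2])
      ph <- stats::runif(1, 0, 2 * pi)
      if (stats::runif(1) < 0.5) th <- pi - th
      a <- stats::runif(1, area_range_um2[1], area_range_um2[2])
      r <- sqrt(a / pi)
      p <- c(semi_axes_um[1] * sin(th) * cos(ph),
             semi_axes_um[2] * sin(th) * sin(ph),
             semi_axes_um[3] * cos(th))
      ok <- TRUE
      if (!is.null(centers)) {
        for (j in seq_len(nrow(centers)))
          if (sqrt(sum((p - centers[j, 1:3])^2)) <
              r + centers[j, 4] + min_sep_um) ok <- FALSE
      }
      if (ok) {
        centers <- rbind(centers, c(p, r))
        gaps[[length(gaps) + 1L]] <-
          gap_spec(th, ph, a, stats::runif(1, residual_range[1],
                                           residual_range[2]))
      }
    }
    gaps
  })
}

#' Generate a population of MN with known rupture states
#'
#' Per chromosome class, realized intact counts are Binomial(n, p) draws;
#' the per-MN truth table (and optionally rendered stacks) feeds the
#' statistics stage. Deterministic in `seed`.
#'
#' @param n_per_class Named integer vector of MN counts per class.
#' @param intact_probability Per-class intact probability (recycled).
#' @param spec_template A [synthetic_mn_spec()] used when rendering.
#' @param seed Integer seed.
#' @param render Render a stack per MN via [generate_mn_stack()] (keep n
#'   small when TRUE).
#' @return List: `truth` (data.frame mn_id, class, rupture_state),
#'   `counts` (k x 2 matrix intact/ruptured per class), `stacks` (list or
#'   NULL).
#' @export
generate_population <- function(n_per_class, intact_probability,
                                spec_template = synthetic_mn_spec(),
                                seed = 1L, render = FALSE) {
  if (any(n_per_class < 1)) stop("empty class")
  stopifnot(all(intact_probability >= 0), all(intact_probability <= 1))
  k <- length(n_per_class)
  if (is.null(names(n_per_class))) names(n_per_class) <- paste0("class", seq_len(k))
  p <- rep_len(intact_probability, k)
  .with_seed(seed, {
    rows <- lapply(seq_len(k), function(i) {
      n <- n_per_class[i]
      n_intact <- stats::rbinom(1, n, p[i])
      st <- c(rep("intact", n_intact), rep("ruptured", n - n_intact))
      data.frame(class = names(n_per_class)[i], rupture_state = st,
                 stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
    truth$mn_id <- seq_len(nrow(truth))
    counts <- t(vapply(split(truth$rupture_state, truth$class)[names(n_per_class)],
                       function(s) c(intact = sum(s == "intact"),
                                     ruptured = sum(s == "ruptured")),
                       c(intact = 0, ruptured = 0)))
    stacks <- NULL
    if (render) {
      stacks <- lapply(seq_len(nrow(truth)), function(i) {
        spi <- spec_template
        spi$rupture_state <- truth$rupture_state[i]
        generate_mn_stack(spi, seed = seed * 100003L %% 2147483647L + i)
      })
    }
    list(truth = truth[, c("mn_id", "class", "rupture_state")],
         counts = counts, stacks = stacks)
  })
}

#' Sample a 2x2 contingency table from two binomials
#'
#' Row totals are fixed at `n1`, `n2`; successes are binomial draws (or
#' nearest-integer expected values with `expected = TRUE`, reproducing
#' printed group sizes/percentages exactly).
#'
#' @param n1,n2 Row totals (> 0).
#' @param p1,p2 Success probabilities.
#' @param seed Integer seed (ignored in expected-value mode).
#' @param expected Use nearest-integer expected counts instead of sampling.
#' @return A [contingency_2x2()].
#' @examples
#' generate_contingency(193, 0.948, 116, 0.077, expected = TRUE)
#' @export
generate_contingency <- function(n1, p1, n2, p2, seed = 1L,
                                 expected = FALSE) {
  stopifnot(n1 > 0, n2 > 0, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (expected) {
    x1 <- round(n1 * p1); x2 <- round(n2 * p2)
  } else {
    xs <- .with_seed(seed, c(stats::rbinom(1, n1, p1),
                             stats::rbinom(1, n2, p2)))
    x1 <- xs[1]; x2 <- xs[2]
  }
  contingency_2x2(x1, n1 - x1, x2, n2 - x2)
}

#' Generate toy LAD/blacklist BED fixtures with known coverage
#'
#' Chromosomes are partitioned into random segments; segments are selected
#' (the last one trimmed) so the realized covered fraction matches the
#' request to within rounding, then shuffled along the chromosome.
#' Deterministic in `seed`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param lad_fraction,blacklist_fraction Target covered fractions in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return List: `lads`, `blacklist` (normalized `GRanges`), `lengths`.
#' @export
generate_bed_fixture <- function(chrom_lengths, lad_fraction = 0.3,
                                 blacklist_fraction = 0.05, seed = 1L) {
  stopifnot(lad_fraction >= 0, lad_fraction < 1,
            blacklist_fraction >= 0, blacklist_fraction < 1)
  draw_set <- function(len, frac, chrom) {
    if (frac == 0 || len < 2) return(NULL)
    target <- round(frac * len)
    if (target < 1) return(NULL)
    n_seg <- max(4L, min(60L, floor(len / 500)))
    cuts <- sort(sample.int(len - 1L, n_seg - 1L))
    starts <- c(0, cuts); ends <- c(cuts, len)
    ord <- sample.int(n_seg)
    got <- 0; keep <- integer(0); trim <- NULL
    for (i in ord) {
      w <- ends[i] - starts[i]
      if (got + w <= target) { keep <- c(keep, i); got <- got + w }
      else if (got < target) { trim <- c(i, target - got); got <- target }
      if (got >= target) break
    }
    df <- if (length(keep))
      data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
    else NULL
    if (!is.null(trim))
      df <- rbind(df, data.frame(chrom = chrom, start = starts[trim[1]],
                                 end = starts[trim[1]] + trim[2]))
    df
  }
  .with_seed(seed, {
    lads <- do.call(rbind, c(list(NULL), lapply(names(chrom_lengths), function(ch)
      draw_set(chrom_lengths[[ch]], lad_fraction, ch))))
    bl <- do.call(rbind, c(list(NULL), lapply(names(chrom_lengths), function(ch)
      draw_set(chrom_lengths[[ch]], blacklist_fraction, ch))))
    empty <- GenomicRanges::GRanges()
    list(lads = if (is.null(lads)) empty else genomic_interval_set(lads),
         blacklist = if (is.null(bl)) empty else genomic_interval_set(bl),
         lengths = chrom_lengths)
  })
}
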