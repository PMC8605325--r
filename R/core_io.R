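#' Voxel spacing of an anisotropic image stack
#'
#' Physical sampling of a 3D fluorescence stack. Lateral pixel size is
#' typically ~20 nm for STED acquisitions and the axial step 150 nm, so all
#' geometric code must carry spacing explicitly rather than assume isotropy.
#'
#' @param dx_nm,dy_nm Lateral pixel size in nanometres (must be equal unless
#'   `allow_rectangular = TRUE`).
#' @param dz_nm Axial step in nanometres.
#' @param allow_rectangular Permit `dx_nm != dy_nm`.
#' @return An object of class `voxel_spacing` (named list with `dx_nm`,
#'   `dy_nm`, `dz_nm`).
#' @examples
#' voxel_spacing(20, 20, 150)
#' @export
voxel_spacing <- function(dx_nm, dy_nm = dx_nm, dz_nm, allow_rectangular = FALSE) {
  vals <- c(dx_nm = dx_nm, dy_nm = dy_nm, dz_nm = dz_nm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("voxel spacing values must be strictly positive and finite")
  if (!allow_rectangular && abs(dx_nm - dy_nm) > 1e-9)
    stop("square pixels required (dx_nm == dy_nm); set allow_rectangular = TRUE to override")
  structure(list(dx_nm = dx_nm, dy_nm = dy_nm, dz_nm = dz_nm),
            class = "voxel_spacing")
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing: dx = %g nm, dy = %g nm, dz = %g nm\n",
              x$dx_nm, x$dy_nm, x$dz_nm))
  invisible(x)
}

#' Multi-channel 3D image stack
#'
#' Container for registered fluorescence channels sharing one voxel grid.
#' Arrays are indexed `[z, y, x]` (plane, row, column), 1-based as usual in R;
#' channels are addressed by name everywhere downstream.
#'
#' @param channels Named list of 3D numeric arrays with identical dims.
#' @param spacing A [voxel_spacing()].
#' @param metadata Free-form named list.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(channels, spacing, metadata = list()) {
  if (!is.list(channels) || length(channels) == 0L)
    stop("channels must be a non-empty named list of 3D arrays")
  nm <- names(channels)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("channel names must be unique and non-empty")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3D array indexed [z, y, x]")
  if (length(unique(lapply(dims, as.integer))) != 1L)
    stop("all channels must share identical (z, y, x) dimensions")
  for (ch in nm) {
    if (any(channels[[ch]] < 0))
      stop(sprintf("channel '%s' contains negative intensities", ch))
  }
  stopifnot(inherits(spacing, "voxel_spacing"))
  structure(list(channels = channels, spacing = spacing, metadata = metadata),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("image_stack: %d channel(s) [%s], %d z x %d y x %d x voxels\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3]))
  print(x$spacing)
  invisible(x)
}

#' @rdname image_stack
#' @param x Object to test.
#' @export
is_image_stack <- function(x) inherits(x, "image_stack")

#' Fetch one channel of a stack by name
#'
#' @param stack An [image_stack()].
#' @param name Channel name.
#' @return The 3D array for that channel.
#' @export
stack_channel <- function(stack, name) {
  stopifnot(is_image_stack(stack))
  if (!name %in% names(stack$channels))
    stop(sprintf("unknown channel '%s'; available: %s", name,
                 paste(names(stack$channels), collapse = ", ")))
  stack$channels[[name]]
}

#' Region-of-interest mask tied to an image stack
#'
#' A single connected DNA-positive object: either the main nucleus or a
#' micronucleus (a round DNA-stain object adjacent to but distinct from the
#' nucleus).
#'
#' @param label_id Positive integer label.
#' @param kind `"nucleus"` or `"micronucleus"`.
#' @param mask Logical 3D array (or 2D projected mask).
#' @param check_connected Verify single connectedness (2D masks only;
#'   3D masks are checked plane-wise unions).
#' @return Object of class `region_mask`.
#' @export
region_mask <- function(label_id, kind = c("micronucleus", "nucleus"), mask,
                        check_connected = TRUE) {
  kind <- match.arg(kind)
  if (!is.numeric(label_id) || length(label_id) != 1L || label_id < 1)
    stop("label_id must be a single positive integer")
  if (!is.logical(mask)) stop("mask must be logical")
  if (!sum(mask)) stop("region mask is empty")
  if (check_connected) {
    m2 <- if (length(dim(mask)) == 3L) apply(mask, c(2, 3), any) else mask
    lab <- EBImage::bwlabel(t(m2) * 1)
    if (max(lab) > 1L)
      stop(sprintf("region mask has %d connected components; expected 1", max(lab)))
  }
  structure(list(label_id = as.integer(label_id), kind = kind, mask = mask),
            class = "region_mask")
}

.default_config <- function() {
  list(
    # meshwork segmentation
    filter_scale_nm   = 60,
    n_orientations    = 12L,
    response_quantile = 0.5,
    # gap filters (printed cut-offs)
    theta_area_um2 = 0.12,
    theta_ratio    = 0.5,
    # rupture scoring: ruptured iff MN/nucleus H3K27ac mean ratio < 0.4
    rupture_ratio = 0.4,
    # spot detection
    spot_diameter_um = 0.2,
    spot_threshold   = NA_real_,
    # rim intensity
    rim_width_px    = 4L,
    expand_factor   = 2,
    background_mode = "scaled",
    # statistics
    alpha = 0.05,
    seed  = 1L
  )
}

#' Analysis configuration
#'
#' All tunable parameters of the pipeline with their published defaults:
#' gap area cut-off 0.12 um^2, gap intensity ratio cut-off 0.5, rupture
#' ratio 0.4, spot diameter 0.2 um, alpha 0.05. Unknown keys are rejected
#' rather than ignored so a typo cannot silently change a threshold.
#'
#' @param ... Named overrides of the defaults.
#' @return Object of class `analysis_config` (named list).
#' @examples
#' cfg <- analysis_config(theta_ratio = 0.6)
#' cfg$theta_area_um2  # 0.12
#' @export
analysis_config <- function(...) {
  cfg <- .default_config()
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop(sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", ")))
    numeric_keys <- setdiff(names(cfg), "background_mode")
    for (k in names(ov)) {
      if (k %in% numeric_keys && !is.numeric(ov[[k]]))
        stop(sprintf("configuration key '%s' must be numeric", k))
      cfg[[k]] <- ov[[k]]
    }
  }
  if (!cfg$background_mode %in% c("printed", "scaled", "annulus"))
    stop("background_mode must be one of 'printed', 'scaled', 'annulus'")
  stopifnot(cfg$theta_area_um2 > 0, cfg$theta_ratio > 0)
  structure(cfg, class = "analysis_config")
}

#' Load an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their published defaults; unknown keys are
#' an error.
#'
#' @param path YAML file. An empty file (or one containing only comments)
#'   yields the full default configuration.
#' @return An [analysis_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must contain a key-value mapping")
  do.call(analysis_config, vals)
}

#' Hash of the effective configuration
#'
#' Stable md5 over the deparsed configuration, used in run manifests and
#' cache keys.
#'
#' @param cfg An [analysis_config()].
#' @return md5 hex string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","), ""),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

.meta_path <- function(path) paste0(path, ".meta.json")

#' Write an image stack to TIFF with a JSON metadata sidecar
#'
#' Planes are written channel-major (all z of channel 1, then channel 2, ...)
#' as 32-bit TIFF. `tiff` stores samples on a [0,1] integer scale, so each
#' channel is divided by its recorded maximum; the sidecar
#' (`<path>.meta.json`) carries channel names, voxel spacing and the scale
#' factors so [read_stack()] restores intensities (to ~2^-32 relative).
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(is_image_stack(stack))
  d <- dim(stack$channels[[1]])
  planes <- list()
  scales <- vapply(stack$channels, function(a) max(a, 1e-12), 0)
  for (ci in seq_along(stack$channels)) {
    a <- stack$channels[[ci]] / scales[ci]
    for (z in seq_len(d[1])) planes[[length(planes) + 1L]] <- a[z, , ]
  }
  suppressWarnings(tiff::writeTIFF(planes, path, bits.per.sample = 32L))
  meta <- list(
    channels = names(stack$channels),
    n_z = d[1], n_y = d[2], n_x = d[3],
    spacing = list(dx_nm = stack$spacing$dx_nm, dy_nm = stack$spacing$dy_nm,
                   dz_nm = stack$spacing$dz_nm),
    scales = as.list(stats::setNames(scales, names(stack$channels))),
    metadata = stack$metadata
  )
  jsonlite::write_json(meta, .meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-plane TIFF into an image stack
#'
#' Reads a TIFF written by [write_stack()] (using its sidecar for channel
#' names, spacing and intensity scales) or a plain TIFF, in which case
#' `channel_map` assigns plane blocks to channels and spacing must come from
#' `spacing_override` (an error is raised when no spacing is available from
#' either source).
#'
#' @param path TIFF file.
#' @param channel_map Optional named integer vector mapping channel name to
#'   1-based channel index (plane-block order). Ignored when a sidecar exists.
#' @param spacing_override Optional [voxel_spacing()] taking precedence over
#'   file metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = NULL, spacing_override = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  if (length(planes) < 1L) stop("TIFF contains no planes")
  meta <- NULL
  if (file.exists(.meta_path(path)))
    meta <- jsonlite::read_json(.meta_path(path), simplifyVector = TRUE)

  if (!is.null(meta)) {
    ch_names <- meta$channels
    n_z <- meta$n_z
    scales <- unlist(meta$scales)[ch_names]
  } else {
    if (is.null(channel_map)) channel_map <- c(channel1 = 1L)
    ch_names <- names(channel_map)
    if (length(planes) %% length(ch_names) != 0L)
      stop("plane count is not a multiple of the channel count")
    n_z <- length(planes) %/% length(ch_names)
    if (any(channel_map < 1L | channel_map > length(ch_names)))
      stop("channel index out of range")
    scales <- stats::setNames(rep(1, length(ch_names)), ch_names)
  }

  spacing <- spacing_override
  if (is.null(spacing) && !is.null(meta))
    spacing <- voxel_spacing(meta$spacing$dx_nm, meta$spacing$dy_nm,
                             meta$spacing$dz_nm)
  if (is.null(spacing))
    stop("spacing unavailable: no metadata sidecar and no spacing_override")

  d2 <- dim(planes[[1]])
  channels <- list()
  for (ci in seq_along(ch_names)) {
    idx <- if (!is.null(meta)) ci else unname(channel_map[ch_names[ci]])
    a <- array(0, dim = c(n_z, d2[1], d2[2]))
    for (z in seq_len(n_z)) a[z, , ] <- planes[[(idx - 1L) * n_z + z]]
    channels[[ch_names[ci]]] <- a * scales[ch_names[ci]]
  }
  image_stack(channels, spacing, metadata = if (is.null(meta)) list() else
    as.list(meta$metadata))
}

.measurement_columns <- c(
  "label_id", "kind", "rupture_call", "n_centromere_foci", "area_um2",
  "volume_um3", "surface_um2", "laminB1_FN", "laminB1_norm", "spot_count",
  "spot_density", "gap_count", "gap_density", "has_gap")

#' Assemble a per-MN measurement row
#'
#' One row of the per-object output table; missing measurements are `NA`.
#'
#' @param label_id Integer object label.
#' @param kind `"micronucleus"` or `"nucleus"`.
#' @param ... Any of the measurement columns (see
#'   [write_measurements()]).
#' @return A one-row data.frame with the canonical column order.
#' @export
mn_measurement <- function(label_id, kind = "micronucleus", ...) {
  row <- list(label_id = as.integer(label_id), kind = kind,
              rupture_call = NA_character_, n_centromere_foci = NA_integer_,
              area_um2 = NA_real_, volume_um3 = NA_real_, surface_um2 = NA_real_,
              laminB1_FN = NA_real_, laminB1_norm = NA_real_,
              spot_count = NA_integer_, spot_density = NA_real_,
              gap_count = NA_integer_, gap_density = NA_real_, has_gap = NA)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(row))
  if (length(unknown))
    stop(sprintf("unknown measurement field(s): %s", paste(unknown, collapse = ", ")))
  row[names(ov)] <- ov
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Write per-MN measurements to CSV
#'
#' Fixed, documented column order (`label_id, kind, rupture_call,
#' n_centromere_foci, area_um2, volume_um3, surface_um2, laminB1_FN,
#' laminB1_norm, spot_count, spot_density, gap_count, gap_density, has_gap`);
#' floats are written at 6 significant digits. An empty input produces a
#' header-only file.
#'
#' @param rows data.frame of measurement rows (as from [mn_measurement()]),
#'   or a list of such one-row frames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows))
    rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.measurement_columns))),
      .measurement_columns)
  }
  missing_cols <- setdiff(.measurement_columns, names(rows))
  for (mc in missing_cols) rows[[mc]] <- NA
  rows <- rows[, .measurement_columns]
  num <- vapply(rows, is.numeric, TRUE) & !vapply(rows, is.integer, TRUE)
  rows[num] <- lapply(rows[num], signif, digits = 6)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return data.frame with the canonical columns.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(kind = "character",
                                 rupture_call = "character"))
}

#' Append a timestamped line to a run log
#'
#' @param logfile Path to a plain-text log (created if absent); `NULL` is a
#'   no-op.
#' @param ... Message parts, pasted together.
#' @return Invisibly, the formatted line.
#' @export
log_line <- function(logfile, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  paste0(..., collapse = ""))
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE, sep = "")
  invisible(line)
}
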