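.stack_points_um <- function(channel, spacing, mask = NULL, threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.3 * max(channel)
  sel <- channel > threshold
  if (!is.null(mask)) sel <- sel & mask
  idx <- which(sel, arr.ind = TRUE)
  cbind(x = (idx[, 3] - 1) * spacing$dx_nm,
        y = (idx[, 2] - 1) * spacing$dy_nm,
        z = (idx[, 1] - 1) * spacing$dz_nm) / 1000
}

#' Measure one MN stack end to end
#'
#' Applies every measurement stage to one (synthetic or real) MN stack given
#' its region masks: lamina gap analysis, projected area, ellipsoid/hull
#' volume and sphere-equivalent surface, rupture call, centromere count, rim
#' lamin B1 intensity normalized to the nucleus, and spot density.
#'
#' @param stack An [image_stack()].
#' @param mn_mask3 3D logical MN interior mask.
#' @param nucleus_mask3 Optional 3D logical nucleus mask (rupture reference
#'   and rim normalization).
#' @param config An [analysis_config()].
#' @param label_id Label for the output row.
#' @return List: `row` (one [mn_measurement()] row), `gaps` (candidate
#'   table).
#' @export
measure_mn_stack <- function(stack, mn_mask3, nucleus_mask3 = NULL,
                             config = analysis_config(), label_id = 1L) {
  sp <- stack$spacing
  footprint <- apply(mn_mask3, c(2, 3), any)
  chans <- names(stack$channels)

  gaps <- NULL; gap_summary <- list(gap_count = NA_integer_, has_gap = NA,
                                    gap_density = NA_real_)
  volume <- list(v_mn_um3 = NA_real_, surface_um2 = NA_real_)
  if ("lamin" %in% chans) {
    ga <- analyze_mn_gaps(stack, footprint, config)
    gaps <- ga$gaps
    gap_summary <- ga$summary
    # lamin-positive voxels: gate on smoothed raw signal against the
    # footprint's background quartile (same gate as the segmentation), so
    # both the bright rim and the dim pole are kept while empty planes and
    # the interior are not
    lam <- stack_channel(stack, "lamin")
    s_px <- config$filter_scale_nm / sp$dx_nm
    sm3 <- gaussian_smooth_3d(lam, c(0, s_px, s_px))
    mn_region <- array(rep(footprint, each = dim(lam)[1]), dim(lam))
    if (!is.null(nucleus_mask3)) mn_region <- mn_region & !nucleus_mask3
    gate <- 2.5 * stats::quantile(sm3[mn_region], 0.25)
    pts <- .stack_points_um(sm3, sp, mask = mn_region, threshold = gate)
    # tolerance 1e-3: the optimality gap is far below the 20 nm voxelization
    # error of the point cloud, at a fraction of the cost
    if (nrow(pts) >= 10) volume <- mn_volume_surface(pts, tolerance = 1e-3)
  }

  rupture <- NA_character_
  if ("h3k27ac" %in% chans && !is.null(nucleus_mask3)) {
    h3 <- stack_channel(stack, "h3k27ac")
    rc <- classify_rupture(mean(h3[mn_mask3]), mean(h3[nucleus_mask3]),
                           config$rupture_ratio)
    rupture <- rc$call
  }

  n_cen <- NA_integer_
  if ("centromere" %in% chans) {
    cen <- detect_spots(stack_channel(stack, "centromere"), sp,
                        diameter_um = 0.3, threshold = NA)
    n_cen <- chromosome_count(cen, mn_mask3, sp)
  }

  spot_count <- NA_integer_; spot_dens <- NA_real_
  if ("spots" %in% chans && is.finite(volume$surface_um2)) {
    # NPC foci sit on the shell, half outside the interior footprint:
    # include a margin of one spot diameter around it
    marg <- max(3L, round(config$spot_diameter_um * 1000 / sp$dx_nm))
    fp_d <- t(EBImage::dilate(t(footprint) * 1,
                              EBImage::makeBrush(2L * marg + 1L, "disc"))) > 0.5
    shell_region <- array(rep(fp_d, each = dim(mn_mask3)[1]),
                          dim(mn_mask3))
    if (!is.null(nucleus_mask3)) shell_region <- shell_region & !nucleus_mask3
    spt <- detect_spots(stack_channel(stack, "spots"), sp,
                        diameter_um = config$spot_diameter_um,
                        threshold = if (is.na(config$spot_threshold)) NA else
                          config$spot_threshold,
                        mask = shell_region)
    spot_count <- spt$count
    spot_dens <- spot_density(spt, volume$surface_um2)$density_um2
  }

  fn <- NA_real_; fnorm <- NA_real_
  if ("lamin" %in% chans) {
    lam <- stack_channel(stack, "lamin")
    z_eq <- find_equatorial_plane(lam, footprint)
    mn_rim <- measure_rim(lam[z_eq, , ], footprint,
                          width_px = config$rim_width_px,
                          factor = config$expand_factor,
                          mode = config$background_mode)
    fn <- mn_rim$F_N
    if (!is.null(nucleus_mask3)) {
      zc <- round(dim(nucleus_mask3)[1] / 2)
      nmask2 <- nucleus_mask3[zc, , ]
      if (sum(nmask2) > 0) {
        nuc_rim <- measure_rim(lam[zc, , ], nmask2,
                               width_px = config$rim_width_px,
                               factor = config$expand_factor,
                               mode = config$background_mode)
        fnorm <- suppressWarnings(normalized_rim_intensity(mn_rim, nuc_rim))
      }
    }
  }

  row <- mn_measurement(
    label_id = label_id, kind = "micronucleus", rupture_call = rupture,
    n_centromere_foci = as.integer(n_cen),
    area_um2 = mn_area(footprint, sp),
    volume_um3 = volume$v_mn_um3, surface_um2 = volume$surface_um2,
    laminB1_FN = fn, laminB1_norm = fnorm,
    spot_count = as.integer(spot_count), spot_density = spot_dens,
    gap_count = as.integer(gap_summary$gap_count),
    gap_density = gap_summary$gap_density, has_gap = gap_summary$has_gap)
  list(row = row, gaps = gaps)
}

#' Run the full simulate-measure-test pipeline
#'
#' Generates a population of synthetic MN with known rupture states, runs
#' every measurement stage on each rendered stack, writes the measurement
#' and gap tables, applies the family-gated statistics to the per-class
#' rupture counts, and records a run manifest. Re-running with an unchanged
#' configuration and seed is a no-op returning the cached manifest.
#'
#' @param config An [analysis_config()].
#' @param out_dir Output directory (created).
#' @param n_per_class Named MN counts per chromosome class.
#' @param intact_probability Per-class intact probabilities.
#' @param spec_template A [synthetic_mn_spec()].
#' @param seed Integer seed (default from `config`).
#' @param force Re-run even when cached outputs match.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = analysis_config(), out_dir,
                         n_per_class = c(A = 5L, B = 5L),
                         intact_probability = c(0.9, 0.3),
                         spec_template = synthetic_mn_spec(),
                         seed = config$seed, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  logfile <- file.path(out_dir, "run.log")
  chash <- config_hash(config)
  key <- paste0(chash, ":", seed, ":",
                paste(names(n_per_class), n_per_class, intact_probability,
                      collapse = ","))
  outputs <- file.path(out_dir, c("measurements.csv", "gaps.csv",
                                  "stats.json"))
  if (!force && file.exists(manifest_path)) {
    prev <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (identical(prev$cache_key, key) && all(file.exists(outputs))) {
      log_line(logfile, "cache hit; skipping run (key ", key, ")")
      return(invisible(prev))
    }
  }
  log_line(logfile, "run start; config ", chash, "; seed ", seed)

  stage <- "simulate"
  res <- tryCatch({
    pop <- generate_population(n_per_class, intact_probability,
                               spec_template, seed = seed, render = TRUE)
    stage <- "measure"
    rows <- list(); gap_tables <- list()
    for (i in seq_along(pop$stacks)) {
      st <- pop$stacks[[i]]
      m <- measure_mn_stack(st$stack, st$truth$interior,
                            st$truth$nucleus_mask, config, label_id = i)
      rows[[i]] <- m$row
      if (!is.null(m$gaps) && nrow(m$gaps)) {
        m$gaps$label_id <- i
        gap_tables[[length(gap_tables) + 1L]] <- m$gaps
      }
    }
    meas <- do.call(rbind, rows)
    meas$class <- pop$truth$class
    write_measurements(meas[, setdiff(names(meas), "class")], outputs[1])
    gdf <- if (length(gap_tables)) do.call(rbind, gap_tables) else
      data.frame()
    utils::write.csv(gdf, outputs[2], row.names = FALSE)

    stage <- "stats"
    counts <- t(vapply(split(meas$rupture_call, pop$truth$class),
                       function(s) c(intact = sum(s == "intact"),
                                     ruptured = sum(s == "ruptured")),
                       c(intact = 0, ruptured = 0)))
    if (nrow(counts) >= 2L) {
      hc <- hierarchical_compare(counts, alpha = config$alpha)
      stats_out <- list(
        family = list(method = hc$family$method,
                      statistic = hc$family$statistic,
                      df = hc$family$df, p_value = hc$family$p_value),
        branch = hc$branch,
        pairwise = hc$pairwise)
    } else {
      hc <- NULL
      stats_out <- list(note = "fewer than 2 classes; no family test")
    }
    jsonlite::write_json(stats_out, outputs[3], auto_unbox = TRUE,
                         digits = NA, na = "null")
    list(measurements = meas, counts = counts, stats = hc)
  }, error = function(e) {
    log_line(logfile, "FAILED at stage ", stage, ": ", conditionMessage(e))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    cache_key = key, config_hash = chash, seed = seed,
    package_version = as.character(utils::packageVersion("mnlamina")),
    stages = c("simulate", "measure", "stats"),
    outputs = basename(outputs),
    n_per_class = as.list(n_per_class),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_line(logfile, "run complete; outputs: ",
           paste(basename(outputs), collapse = ", "))
  invisible(c(manifest, list(result = res)))
}
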