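.box_brush <- function(width_px) {
  matrix(1L, 2L * width_px + 1L, 2L * width_px + 1L)
}

#' Inner rim band of a region mask
#'
#' The published lamin B1 readout converts the object outline to a
#' four-pixel border: here, the set difference between the mask and its
#' erosion by `width_px` (box structuring element). When the erosion empties
#' (object thinner than twice the width) the whole mask is returned and
#' flagged.
#'
#' @param mask 2D logical mask (non-empty).
#' @param width_px Rim width in pixels (default 4).
#' @return Logical mask of the rim band, with attribute `flagged` when the
#'   erosion emptied.
#' @export
rim_selection <- function(mask, width_px = 4L) {
  stopifnot(width_px >= 1L)
  if (!sum(mask)) stop("mask is empty")
  er <- t(EBImage::erode(t(mask) * 1, .box_brush(width_px))) > 0.5
  if (!any(er)) {
    rim <- mask
    attr(rim, "flagged") <- TRUE
    return(rim)
  }
  rim <- mask & !er
  attr(rim, "flagged") <- FALSE
  rim
}

#' Expand a selection by repeated dilation to a target area
#'
#' Dilates (3x3 box) until the area reaches `factor` times the input area.
#' If the growing selection touches the image border before the target is
#' reached the result is flagged (background estimate may be truncated) but
#' returned.
#'
#' @param rim 2D logical mask.
#' @param factor Target area multiple (>= 2, per the published procedure).
#' @return Expanded logical mask with attribute `flagged`.
#' @export
expand_selection <- function(rim, factor = 2) {
  if (factor < 2) stop("expansion factor must be >= 2")
  a0 <- sum(rim)
  if (!a0) stop("rim mask is empty")
  target <- factor * a0
  cur <- rim
  d <- dim(rim)
  flagged <- FALSE
  touches_border <- function(m) any(m[1, ]) || any(m[d[1], ]) ||
    any(m[, 1]) || any(m[, d[2]])
  repeat {
    if (sum(cur) >= target) break
    if (touches_border(cur)) flagged <- TRUE
    nxt <- t(EBImage::dilate(t(cur) * 1, .box_brush(1L))) > 0.5
    if (sum(nxt) == sum(cur)) { flagged <- TRUE; break }  # saturated
    cur <- nxt
  }
  attr(cur, "flagged") <- flagged
  cur
}

#' Rim intensity measurement
#'
#' Holds the four published quantities: integrated intensity and area of the
#' rim selection (`F_I`, `A_I`) and of the expanded selection (`F_O`,
#' `A_O`), plus the background-subtracted intensity `F_N` for the chosen
#' mode.
#'
#' @param F_I,A_I,F_O,A_O Integrated intensities and pixel areas;
#'   `A_O > A_I > 0` required.
#' @param mode Background-subtraction mode, see
#'   [background_subtracted_intensity()].
#' @return Object of class `rim_measurement` (includes `F_N`).
#' @export
rim_measurement <- function(F_I, A_I, F_O, A_O, mode = "scaled") {
  if (!(A_O > A_I && A_I > 0)) stop("require A_O > A_I > 0")
  m <- structure(list(F_I = F_I, A_I = A_I, F_O = F_O, A_O = A_O,
                      mode = mode, F_N = NA_real_),
                 class = "rim_measurement")
  m$F_N <- background_subtracted_intensity(m, mode)
  m
}

#' Background-subtracted rim intensity
#'
#' Three readings of the published background formula
#' `F_N = F_I - ((F_O - F_I) / (A_I / A_O))`:
#' \describe{
#'   \item{printed}{the literal printed division,
#'     `F_I - (F_O - F_I) * (A_O / A_I)` — yields negative intensities for
#'     typical inputs and is retained for fidelity only;}
#'   \item{scaled}{`F_I - (F_O - F_I) * (A_I / A_O)` (default) — the
#'     multiplication the printed formula almost certainly intends,
#'     approximating the annulus correction when `A_O >> A_I`;}
#'   \item{annulus}{`F_I - A_I * (F_O - F_I) / (A_O - A_I)` — the exact
#'     per-pixel background estimate from the surrounding annulus, 0 on any
#'     uniform image.}
#' }
#'
#' @param m A [rim_measurement()] (or list with `F_I`, `A_I`, `F_O`, `A_O`).
#' @param mode `"printed"`, `"scaled"` or `"annulus"`.
#' @return `F_N`.
#' @export
background_subtracted_intensity <- function(m, mode = c("scaled", "printed",
                                                        "annulus")) {
  mode <- match.arg(mode)
  if (!(m$A_O > m$A_I && m$A_I > 0)) stop("require A_O > A_I > 0")
  db <- m$F_O - m$F_I
  switch(mode,
         printed = m$F_I - db * (m$A_O / m$A_I),
         scaled  = m$F_I - db * (m$A_I / m$A_O),
         annulus = m$F_I - m$A_I * db / (m$A_O - m$A_I))
}

#' Measure rim intensity of an object in one plane
#'
#' Convenience wrapper: builds the rim band and expanded selection from an
#' object mask and integrates a (lamin B1) intensity plane over both.
#'
#' @param plane 2D intensity matrix.
#' @param mask 2D logical object mask (from the chromatin channel, per the
#'   published procedure).
#' @param width_px Rim width (default 4).
#' @param factor Expansion factor (default 2).
#' @param mode Background mode.
#' @return A [rim_measurement()] with attribute `flagged` when either
#'   morphological step was flagged.
#' @export
measure_rim <- function(plane, mask, width_px = 4L, factor = 2,
                        mode = "scaled") {
  rim <- rim_selection(mask, width_px)
  ex <- expand_selection(rim, factor)
  m <- rim_measurement(F_I = sum(plane[rim]), A_I = sum(rim),
                       F_O = sum(plane[ex]), A_O = sum(ex), mode = mode)
  attr(m, "flagged") <- isTRUE(attr(rim, "flagged")) ||
    isTRUE(attr(ex, "flagged"))
  m
}

#' MN rim intensity normalized to the nucleus
#'
#' @param mn,nucleus [rim_measurement()]s computed with the same mode.
#' @return Ratio `mn$F_N / nucleus$F_N`, or `NA` (with a warning) when the
#'   nucleus value is non-positive.
#' @export
normalized_rim_intensity <- function(mn, nucleus) {
  if (!identical(mn$mode, nucleus$mode))
    stop("MN and nucleus measurements must use the same background mode")
  if (!is.finite(nucleus$F_N) || nucleus$F_N <= 0) {
    warning("non-positive nucleus F_N; returning NA")
    return(NA_real_)
  }
  mn$F_N / nucleus$F_N
}

#' Photometric rupture call from H3K27ac means
#'
#' Ruptured MN lose nucleo-cytoplasmic compartmentalization and with it
#' their H3K27ac signal: the call is `ruptured` iff the MN/nucleus mean
#' ratio is strictly below `ratio_cut` (default 0.4, i.e. a > 60% decrease);
#' a ratio of exactly 0.40 is intact. The call is invariant to rescaling
#' both means.
#'
#' @param mn_mean,nuc_mean H3K27ac channel means (nucleus > 0).
#' @param ratio_cut Decision threshold (default 0.4).
#' @return List of class `rupture_call`: `mn_mean`, `nuc_mean`, `ratio`,
#'   `call` (`"intact"`/`"ruptured"`).
#' @export
classify_rupture <- function(mn_mean, nuc_mean, ratio_cut = 0.4) {
  if (nuc_mean <= 0) stop("nucleus mean must be positive")
  ratio <- mn_mean / nuc_mean
  structure(list(mn_mean = mn_mean, nuc_mean = nuc_mean, ratio = ratio,
                 call = if (ratio < ratio_cut) "ruptured" else "intact"),
            class = "rupture_call")
}

#' FISH positivity rule
#'
#' A FISH focus is positive iff its peak is at least twice the local
#' background (inclusive) and it partially co-localizes with a centromere
#' focus.
#'
#' @param focus_peak Peak intensity of the FISH focus.
#' @param local_background Local background level (> 0).
#' @param overlaps_centromere Logical.
#' @return Logical.
#' @export
fish_positive <- function(focus_peak, local_background, overlaps_centromere) {
  if (local_background <= 0) stop("local background must be positive")
  (focus_peak >= 2 * local_background) && isTRUE(overlaps_centromere)
}

#' Chromosome count of an MN from centromere foci
#'
#' Chromosome number is defined as the number of centromere foci whose
#' (refined) coordinates fall inside the MN mask.
#'
#' @param centromere_spots A [detect_spots()] result.
#' @param mn_mask 2D `[y, x]` or 3D `[z, y, x]` logical mask.
#' @param spacing A [voxel_spacing()] used to map um coordinates to voxels.
#' @return Integer count.
#' @export
chromosome_count <- function(centromere_spots, mn_mask, spacing) {
  stopifnot(inherits(centromere_spots, "spot_set"),
            inherits(spacing, "voxel_spacing"))
  co <- centromere_spots$coordinates_um
  if (!nrow(co)) return(0L)
  zi <- round(co[, 1] * 1000 / spacing$dz_nm) + 1L
  yi <- round(co[, 2] * 1000 / spacing$dy_nm) + 1L
  xi <- round(co[, 3] * 1000 / spacing$dx_nm) + 1L
  d <- dim(mn_mask)
  inside <- logical(nrow(co))
  if (length(d) == 3L) {
    ok <- zi >= 1 & zi <= d[1] & yi >= 1 & yi <= d[2] & xi >= 1 & xi <= d[3]
    inside[ok] <- mn_mask[cbind(zi[ok], yi[ok], xi[ok])]
  } else {
    ok <- yi >= 1 & yi <= d[1] & xi >= 1 & xi <= d[2]
    inside[ok] <- mn_mask[cbind(yi[ok], xi[ok])]
  }
  sum(inside)
}

#' Cell-level inclusion rule on FISH focus count
#'
#' Cells with more than three FISH foci for the probed chromosome are
#' excluded (tetraploid or poor signal-to-noise). Zero foci is included but
#' flagged (no evidence of the probed chromosome).
#'
#' @param fish_focus_count Integer per-cell FISH focus count.
#' @return List: `include` (logical), `reason` (string or NA), `flagged`.
#' @export
apply_inclusion_rules <- function(fish_focus_count) {
  stopifnot(fish_focus_count >= 0)
  if (fish_focus_count > 3L)
    return(list(include = FALSE, reason = "FISH foci > 3", flagged = FALSE))
  list(include = TRUE, reason = NA_character_,
       flagged = fish_focus_count == 0L)
}
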