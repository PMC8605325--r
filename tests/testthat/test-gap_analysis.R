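test_that("Brenner focus score matches direct evaluation", {
  expect_equal(brenner_focus(matrix(c(0, 0, 10, 10, 0, 0), nrow = 1)), 400)
  expect_equal(brenner_focus(matrix(7, 10, 10)), 0)
  set.seed(1)
  pl <- matrix(runif(50 * 50), 50)
  # independent oracle: explicit double loop
  s <- 0
  for (y in 1:50) for (x in 1:48) s <- s + (pl[y, x + 2] - pl[y, x])^2
  for (y in 1:48) for (x in 1:50) s <- s + (pl[y + 2, x] - pl[y, x])^2
  expect_equal(brenner_focus(pl), s)
  # blurring strictly decreases the score
  blur <- gaussian_smooth_3d(array(pl, c(1, 50, 50)), c(0, 2, 2))[1, , ]
  expect_lt(brenner_focus(blur), brenner_focus(pl))
})

test_that("equatorial plane search follows the documented tie-breaks", {
  ch <- array(0, c(3, 10, 10))
  ch[1, 4:6, 4:6] <- matrix(c(0, 9, 0, 9, 0, 9, 0, 9, 0), 3)
  expect_equal(find_equatorial_plane(ch), 1L)
  # two tied planes equidistant from the middle: lower index wins
  ch2 <- array(0, c(21, 12, 12))
  pat <- matrix(runif(144), 12)
  ch2[9, , ] <- pat; ch2[13, , ] <- pat
  expect_equal(find_equatorial_plane(ch2), 9L)
  expect_error(find_equatorial_plane(array(0, c(5, 8, 8))), "all-zero")
  expect_error(find_equatorial_plane(array(1, c(2, 8, 8))), "3 z-planes")
})

test_that("generated spheroids put the Brenner equator at the geometric equator", {
  for (s in c(2, 14)) {
    g <- generate_mn_stack(synthetic_mn_spec(), 600 + s)
    ch <- stack_channel(g$stack, "lamin")
    z <- find_equatorial_plane(ch, g$truth$footprint)
    expect_lte(abs(z - g$truth$equator_z), 1)
  }
})

test_that("hemisphere split assigns the equator to the bottom and projects correctly", {
  mask <- array(FALSE, c(4, 6, 6))
  mask[1, 2, 2] <- TRUE; mask[3, 4, 4] <- TRUE
  lam <- array(seq_len(4 * 36) / 10, c(4, 6, 6))
  pr <- split_and_project(mask, 1L, lam)
  expect_true(pr$bottom$binary[2, 2])
  expect_equal(sum(pr$bottom$binary), 1)
  expect_true(pr$top$binary[4, 4])
  expect_equal(pr$bottom$intensity, lam[1, , ])          # single plane mean
  pr4 <- split_and_project(mask, 4L, lam)
  expect_true(pr4$top$empty)
  expect_equal(sum(pr4$bottom$binary), 2)
  allf <- split_and_project(array(FALSE, c(4, 6, 6)), 2L, lam)
  expect_equal(sum(allf$bottom$binary) + sum(allf$top$binary), 0)
  expect_error(split_and_project(mask, 9L, lam), "out of range")
  # max-projection option
  prmax <- split_and_project(mask, 2L, lam, method = "max")
  expect_equal(prmax$bottom$intensity, pmax(lam[1, , ], lam[2, , ]))
})

test_that("gap candidates carry the published descriptors", {
  n <- 60
  fp <- matrix(FALSE, n, n); fp[6:55, 6:55] <- TRUE
  mesh <- fp                                     # fully covered: no holes
  sp <- voxel_spacing(20, 20, 150)
  ii <- matrix(100, n, n)
  expect_equal(nrow(measure_gap_candidates(mesh, ii, fp, sp)), 0)

  # 20x20 square hole at 20 nm pixels -> 0.16 um^2, round-ish, solid
  mesh2 <- fp; mesh2[21:40, 21:40] <- FALSE
  ii2 <- ii; ii2[21:40, 21:40] <- 0
  cands <- measure_gap_candidates(mesh2, ii2, fp, sp)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$area_um2, 400 * 0.02^2)
  expect_lt(cands$eccentricity, 0.1)
  expect_gte(cands$solidity, 0.95)
  expect_equal(cands$mfi_ratio, 0)
  expect_gt(cands$perimeter_um, 1.4)   # boundary walk of a 20 px square

  # hole touching the footprint boundary is not a candidate
  mesh3 <- fp; mesh3[6:20, 6:20] <- FALSE
  expect_equal(nrow(measure_gap_candidates(mesh3, ii, fp, sp)), 0)
  expect_error(measure_gap_candidates(mesh, ii, fp & FALSE, sp), "empty")
})

test_that("gap filters apply the printed cut-offs with strict inequalities", {
  cands <- data.frame(hemisphere = "top",
                      area_um2 = c(0.10, 0.20, 0.20, 0.12),
                      perimeter_um = 1, eccentricity = 0.2, solidity = 0.9,
                      mfi_ratio = c(0.3, 0.3, 0.6, 0.5),
                      passes_area = NA, passes_intensity = NA, accepted = NA)
  out <- filter_gaps(cands, gap_filter_params())
  expect_equal(sum(out$accepted), 1)
  expect_true(out$accepted[2])                    # only (0.20, 0.3)
  expect_false(out$accepted[4])                   # exactly at both cut-offs
  expect_equal(out$accepted, out$passes_area & out$passes_intensity)
})

test_that("filter is monotone in its two thresholds", {
  set.seed(9)
  cands <- data.frame(hemisphere = "top", area_um2 = runif(40, 0.01, 0.5),
                      perimeter_um = 1, eccentricity = 0.5, solidity = 0.9,
                      mfi_ratio = runif(40), passes_area = NA,
                      passes_intensity = NA, accepted = NA)
  n_at <- function(a, r) sum(filter_gaps(cands, gap_filter_params(a, r))$accepted)
  areas <- c(0.05, 0.12, 0.2, 0.4)
  expect_true(all(diff(vapply(areas, n_at, 0, r = 0.5)) <= 0))
  ratios <- c(0.8, 0.5, 0.3, 0.1)
  expect_true(all(diff(vapply(ratios, n_at, 0, a = 0.12)) <= 0))
})

test_that("gap summaries follow the at-least-one rule and density definition", {
  gaps0 <- data.frame(area_um2 = numeric(0), accepted = logical(0))
  s0 <- summarize_gaps(gaps0, 10)
  expect_false(s0$has_gap)
  expect_true(is.na(s0$gap_density))
  gaps3 <- data.frame(area_um2 = c(0.2, 0.3, 0.25), accepted = TRUE)
  s3 <- summarize_gaps(gaps3, 10)
  expect_equal(s3$gap_count, 3)
  expect_true(s3$has_gap)
  expect_equal(s3$gap_density, 0.3)
  expect_error(summarize_gaps(gaps3, 0), "mn_area")
})

test_that("inserted gaps are recovered end to end", {
  gaps <- list(gap_spec(0.45, 0.8, 0.25, 0), gap_spec(2.75, 3.6, 0.25, 0.1))
  g <- generate_mn_stack(synthetic_mn_spec(gaps = gaps), 77)
  res <- analyze_mn_gaps(g$stack, g$truth$footprint)
  expect_equal(res$summary$gap_count, 2)
  expect_true(res$summary$has_gap)
  acc <- res$gaps[res$gaps$accepted, ]
  expect_setequal(acc$hemisphere, c("top", "bottom"))
  expect_equal(sort(acc$area_um2), sort(g$truth$gaps$realized_area_um2),
               tolerance = 0.2)
})
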