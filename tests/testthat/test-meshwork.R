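# rasterize a straight bright line of Gaussian cross-section through the
# plane center at angle theta (line direction), width sigma_px
line_plane <- function(n, theta, sigma_px, amplitude = 1) {
  ctr <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  # signed distance to the line through the center with direction theta
  d <- -(xs - ctr) * sin(theta) + (ys - ctr) * cos(theta)
  amplitude * exp(-d^2 / (2 * sigma_px^2))
}

sp20 <- voxel_spacing(20, 20, 150)

test_that("constant planes give zero ridge response", {
  ch <- array(5, c(2, 40, 40))
  rr <- steerable_ridge_response(ch, sp20)
  expect_true(all(rr$response == 0))
  expect_true(all(is.na(rr$orientation)))
})

test_that("a straight line is localized and oriented correctly", {
  n <- 81
  for (ang in c(pi / 6, pi / 3, 2 * pi / 3)) {
    pl <- line_plane(n, ang, sigma_px = 3)
    rr <- steerable_ridge_response(array(pl, c(1, n, n)), sp20,
                                   scale_nm = 60, n_orientations = 12L)
    r <- rr$response[1, , ]
    interior <- 20:(n - 20)
    # the response crest should sit on the true centerline (+-1 px):
    # the line through the center with direction ang has row = ctr +
    # (col - ctr) tan(ang)
    ctr <- (n + 1) / 2
    for (col in interior) {
      true_row <- ctr + (col - ctr) * tan(ang)
      if (true_row < min(interior) + 2 || true_row > max(interior) - 2) next
      peak_row <- which.max(r[interior, col]) + min(interior) - 1
      expect_lte(abs(peak_row - true_row), 1.5)
    }
    # orientation at the center within 5 degrees (mod pi)
    o <- rr$orientation[1, round(ctr), round(ctr)]
    dtheta <- abs(((o - ang + pi / 2) %% pi) - pi / 2)
    expect_lt(dtheta * 180 / pi, 5)
  }
})

test_that("12 orientations approximate dense orientation sampling", {
  n <- 81
  pl <- line_plane(n, 0.53, sigma_px = 3)
  rr12 <- steerable_ridge_response(array(pl, c(1, n, n)), sp20,
                                   n_orientations = 12L)
  rr180 <- steerable_ridge_response(array(pl, c(1, n, n)), sp20,
                                    n_orientations = 180L)
  interior <- cbind(1, 20:60, 20:60)
  a <- rr12$response[1, 20:60, 20:60]
  b <- rr180$response[1, 20:60, 20:60]
  keep <- b > 0.1 * max(b)
  expect_lt(max(abs(a[keep] - b[keep]) / b[keep]), 0.01)
})

test_that("response is steerable under 90-degree rotation", {
  set.seed(4)
  n <- 64
  pl <- matrix(0, n, n)
  for (i in 1:4) pl <- pl + line_plane(n, runif(1, 0, pi), 3, runif(1, 0.5, 1))
  rr <- steerable_ridge_response(array(pl, c(1, n, n)), sp20,
                                 n_orientations = 36L)
  plr <- t(pl)[n:1, ]                       # rotate 90 degrees
  rrr <- steerable_ridge_response(array(plr, c(1, n, n)), sp20,
                                  n_orientations = 36L)
  a <- rr$response[1, , ]
  b <- rrr$response[1, , ]
  br <- t(b[n:1, ])                          # rotate back
  i <- 15:(n - 15)
  rel_rms <- sqrt(mean((a[i, i] - br[i, i])^2)) / sqrt(mean(a[i, i]^2))
  expect_lt(rel_rms, 0.01)
})

test_that("non-maximum suppression keeps one-pixel crests", {
  n <- 61
  pl <- line_plane(n, 0, sigma_px = 2.5)     # horizontal-direction line?
  rr <- steerable_ridge_response(array(pl, c(1, n, n)), sp20)
  nms <- non_maximum_suppression(rr)
  # each column crossed by the line keeps exactly one pixel (interior)
  for (col in 20:40) {
    hits <- which(nms[1, , col])
    hits <- hits[hits > 10 & hits < n - 10]
    expect_equal(length(hits), 1)
    if (length(hits) == 1) expect_lte(abs(hits - (n + 1) / 2), 1)
  }
  # flat field: empty mask
  flat <- steerable_ridge_response(array(1, c(1, 30, 30)), sp20)
  expect_equal(sum(non_maximum_suppression(flat)), 0)
})

test_that("two parallel ridges yield two disjoint crests", {
  n <- 61
  pl <- matrix(0, n, n)
  d1 <- row(pl) - 25; d2 <- row(pl) - 35
  pl <- exp(-d1^2 / (2 * 2.5^2)) + exp(-d2^2 / (2 * 2.5^2))
  rr <- steerable_ridge_response(array(pl, c(1, n, n)), sp20)
  nms <- non_maximum_suppression(rr)
  crest <- nms[1, , 25:35]
  lab <- t(EBImage::bwlabel(t(crest) * 1))
  expect_equal(max(lab), 2)
})

test_that("segmentation is contrast-invariant, translation-equivariant and deterministic", {
  set.seed(6)
  n <- 64
  pl <- line_plane(n, 1.1, 3) + line_plane(n, 2.4, 3, 0.7) +
    0.02 * matrix(runif(n * n), n)
  ch <- array(pl, c(1, n, n))
  seg1 <- segment_meshwork(ch, sp20, params = list(gate_frac = 0))
  segk <- segment_meshwork(ch * 7.3, sp20, params = list(gate_frac = 0))
  expect_equal(seg1$centerline_mask, segk$centerline_mask)
  seg1b <- segment_meshwork(ch, sp20, params = list(gate_frac = 0))
  expect_identical(seg1$centerline_mask, seg1b$centerline_mask)
  # whole-pixel shift moves ridge response and NMS mask identically:
  # compare two overlapping crops of one larger field (no wrap seam)
  big <- line_plane(n + 10, 0.9, 3) + line_plane(n + 10, 2.2, 3, 0.8)
  crop1 <- array(big[1:n, 1:n], c(1, n, n))
  sh <- 5L
  crop2 <- array(big[(1 + sh):(n + sh), 1:n], c(1, n, n))
  rr1 <- steerable_ridge_response(crop1, sp20)
  rr2 <- steerable_ridge_response(crop2, sp20)
  nms1 <- non_maximum_suppression(rr1)
  nms2 <- non_maximum_suppression(rr2)
  i <- 15:(n - 15)
  # compare where the ridge response is meaningful; sub-1% tails feel the
  # different reflective padding of the two crops
  strong <- rr1$response[1, i, i] > 0.01 * max(rr1$response)
  expect_equal(nms2[1, i - sh, i][strong], nms1[1, i, i][strong])
  # degenerate quantile
  segq <- segment_meshwork(ch, sp20, params = list(response_quantile = 1))
  expect_equal(sum(segq$centerline_mask), 0)
})

test_that("noiseless synthetic shells are densely covered by centerlines", {
  spec <- synthetic_mn_spec(poisson_scale = 0, gaussian_sigma = 0,
                            render_nucleus = FALSE)
  g <- generate_mn_stack(spec, 3)
  ch <- stack_channel(g$stack, "lamin")
  seg <- segment_meshwork(ch, g$stack$spacing, footprint = g$truth$footprint)
  proj <- apply(seg$centerline_mask, c(2, 3), any)
  # projected centerlines populate the footprint like a net: within the
  # footprint eroded by the mesh spacing, every pixel is near a centerline
  fp <- g$truth$footprint
  core <- t(EBImage::erode(t(fp) * 1, EBImage::makeBrush(15, "disc"))) > 0.5
  dmap <- EBImage::distmap(t(1 - proj * 1))
  maxdist <- max(t(as.matrix(dmap))[core])
  expect_lt(maxdist * 0.02, 0.2)   # no point further than 0.2 um from mesh
})
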