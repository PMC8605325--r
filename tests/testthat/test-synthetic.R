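test_that("generation is deterministic in (spec, seed)", {
  spec <- small_mn_spec(n_spots = 4L)
  g1 <- generate_mn_stack(spec, 21)
  g2 <- generate_mn_stack(spec, 21)
  expect_identical(g1$stack$channels, g2$stack$channels)
  g3 <- generate_mn_stack(spec, 22)
  expect_false(identical(g1$stack$channels$lamin, g3$stack$channels$lamin))
})

test_that("noiseless gaps render with the requested area and zero interior", {
  spec <- synthetic_mn_spec(gaps = list(gap_spec(0.35, 1.2, 0.25, 0)),
                            poisson_scale = 0, gaussian_sigma = 0,
                            render_nucleus = FALSE)
  g <- generate_mn_stack(spec, 1)
  tr <- g$truth$gaps
  expect_equal(tr$realized_area_um2, 0.25, tolerance = 0.05)
  # lamin intensity at the voxel rows under the footprint center is ~0
  fp <- g$truth$gap_footprints[[1]]
  core <- t(EBImage::erode(t(fp) * 1, EBImage::makeBrush(9, "disc"))) > 0.5
  lam <- g$stack$channels$lamin
  col_max <- apply(lam, c(2, 3), max)
  expect_lt(max(col_max[core]), 0.25 * max(col_max))
})

test_that("closed-form truth fields are exact", {
  spec <- synthetic_mn_spec(semi_axes_um = c(1, 1, 1),
                            spacing = voxel_spacing(40, 40, 150),
                            render_nucleus = FALSE)
  g <- generate_mn_stack(spec, 2)
  expect_equal(g$truth$volume_um3, 4 * pi / 3)
  expect_equal(g$truth$surface_um2, 4 * pi, tolerance = 1e-3)
})

test_that("invalid geometry is rejected", {
  expect_error(synthetic_mn_spec(semi_axes_um = c(0.5, 0.9, 0.3)), "a >= b")
  flat <- synthetic_mn_spec(semi_axes_um = c(1, 1, 0.3))
  expect_error(generate_mn_stack(flat, 1), "fewer than 5 z-planes")
  big <- synthetic_mn_spec(gaps = list(gap_spec(0.4, 0, 4), gap_spec(2.7, 1, 4)))
  expect_error(generate_mn_stack(big, 1), "exceed")
})

test_that("rupture state drives the rendered H3K27ac ratio", {
  gi <- generate_mn_stack(small_mn_spec(rupture_state = "intact"), 5)
  gr <- generate_mn_stack(small_mn_spec(rupture_state = "ruptured"), 5)
  ratio <- function(g) mean(stack_channel(g$stack, "h3k27ac")[g$truth$interior]) /
    mean(stack_channel(g$stack, "h3k27ac")[g$truth$nucleus_mask])
  expect_gt(ratio(gi), 0.7)
  expect_lt(ratio(gr), 0.4)
})

test_that("population truth tables are binomial and deterministic", {
  pop <- generate_population(c(A = 20L), 1.0, seed = 3)
  expect_true(all(pop$truth$rupture_state == "intact"))

  pop2 <- generate_population(c(A = 10000L), 0.5, seed = 8)
  phat <- pop2$counts["A", "intact"] / 10000
  se <- sqrt(0.25 / 10000)
  expect_lt(abs(phat - 0.5), 3 * se)

  pop3 <- generate_population(c(A = 50L, B = 50L), c(0.2, 0.9), seed = 8)
  pop4 <- generate_population(c(A = 50L, B = 50L), c(0.2, 0.9), seed = 8)
  expect_identical(pop3$counts, pop4$counts)
  expect_error(generate_population(c(A = 0L), 0.5), "empty class")
})

test_that("two distant classes are separated by the family test across seeds", {
  reject <- 0
  for (s in 1:40) {
    pop <- generate_population(c(A = 200L, B = 200L), c(0.2, 0.8), seed = s)
    if (chi_square_family(pop$counts)$p_value < 0.05) reject <- reject + 1
  }
  expect_gte(reject, 40 * 0.99)
})

test_that("contingency sampler fixes row totals and honors expected mode", {
  t1 <- generate_contingency(8, 1, 5, 0, seed = 1)
  expect_equal(as.matrix(t1), matrix(c(8, 0, 0, 5), 2),
               ignore_attr = TRUE)
  # expected-value mode reproduces the printed validation table
  te <- generate_contingency(193, 0.948, 116, 0.077, expected = TRUE)
  expect_equal(as.matrix(te), matrix(c(183, 9, 10, 107), 2),
               ignore_attr = TRUE)
  t2 <- generate_contingency(50, 0.4, 60, 0.6, seed = 7)
  t3 <- generate_contingency(50, 0.4, 60, 0.6, seed = 7)
  expect_identical(t2, t3)
  expect_equal(t2$n11 + t2$n12, 50L)
  expect_equal(t2$n21 + t2$n22, 60L)
})

test_that("random gap placement keeps gaps apart and honors bounds", {
  gaps <- random_gap_specs(3, seed = 5)
  expect_equal(length(gaps), 3)
  for (g in gaps) {
    expect_true(g$area_um2 >= 0.15 && g$area_um2 <= 0.5)
    expect_true(g$residual_fraction <= 0.2)
  }
  expect_identical(random_gap_specs(3, seed = 5), gaps)
  expect_equal(length(random_gap_specs(0, seed = 1)), 0)
})

test_that("voxelized gap area approaches the requested area as spacing shrinks", {
  a_req <- 0.3
  realized <- vapply(c(20, 10), function(px) {
    spec <- synthetic_mn_spec(gaps = list(gap_spec(0.4, 0.7, a_req, 0)),
                              spacing = voxel_spacing(px, px, 150),
                              poisson_scale = 0, gaussian_sigma = 0,
                              render_nucleus = FALSE)
    generate_mn_stack(spec, 4)$truth$gaps$realized_area_um2
  }, 0)
  expect_lte(abs(realized[2] - a_req), abs(realized[1] - a_req) + 0.01)
  expect_equal(realized[2], a_req, tolerance = 0.03)
})
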