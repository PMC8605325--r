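test_that("rim selection produces the expected border band", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE   # 10x10 square
  rim1 <- rim_selection(sq, 1L)
  expect_equal(sum(rim1), 36)                            # 100 - 64
  expect_false(attr(rim1, "flagged"))
  rim5 <- rim_selection(sq, 5L)
  expect_equal(sum(rim5), 100)                           # erosion empties
  expect_true(attr(rim5, "flagged"))
  # ring of width 4: its own rim is the whole ring
  ring <- matrix(FALSE, 30, 30); ring[6:25, 6:25] <- TRUE
  ring[10:21, 10:21] <- FALSE
  rimr <- rim_selection(ring, 4L)
  expect_equal(unclass(rimr), unclass(ring), ignore_attr = TRUE)
  expect_error(rim_selection(matrix(FALSE, 5, 5)), "empty")
})

test_that("selection expansion reaches the target area and flags truncation", {
  sq <- matrix(FALSE, 40, 40); sq[15:24, 15:24] <- TRUE
  rim <- rim_selection(sq, 1L)
  ex2 <- expand_selection(rim, 2)
  expect_gte(sum(ex2), 2 * sum(rim))
  expect_false(attr(ex2, "flagged"))
  ex3 <- expand_selection(rim, 3)
  expect_gte(sum(ex3), 3 * sum(rim))
  # one dilation ring of a ~14x14 boundary adds < 4*17 pixels
  expect_lte(sum(ex3), 3 * sum(rim) + 4 * (sqrt(sum(ex3)) + 2))
  corner <- matrix(FALSE, 12, 12); corner[1:4, 1:4] <- TRUE
  exc <- expand_selection(corner, 2)
  expect_true(attr(exc, "flagged"))
  expect_error(expand_selection(rim, 1.5), ">= 2")
})

test_that("background-subtracted intensity implements all three modes", {
  m <- list(F_I = 100, A_I = 10, F_O = 160, A_O = 30)
  expect_equal(background_subtracted_intensity(m, "printed"), -80)
  expect_equal(background_subtracted_intensity(m, "scaled"), 80)
  expect_equal(background_subtracted_intensity(m, "annulus"), 70)
  # zero-background surround: F_N = F_I in every mode
  m0 <- list(F_I = 55, A_I = 10, F_O = 55, A_O = 30)
  for (mode in c("printed", "scaled", "annulus"))
    expect_equal(background_subtracted_intensity(m0, mode), 55)
  # uniform image of value v: annulus mode nulls out exactly
  v <- 3.7
  mu <- list(F_I = 10 * v, A_I = 10, F_O = 30 * v, A_O = 30)
  expect_equal(background_subtracted_intensity(mu, "annulus"), 0)
  expect_error(background_subtracted_intensity(
    list(F_I = 1, A_I = 10, F_O = 2, A_O = 10)), "A_O > A_I")
})

test_that("rim measurement and normalization compose", {
  r1 <- rim_measurement(40, 10, 70, 30, mode = "scaled")
  r2 <- rim_measurement(80, 10, 140, 30, mode = "scaled")
  expect_equal(normalized_rim_intensity(r1, r2), 0.5)
  expect_equal(normalized_rim_intensity(r2, r2), 1)
  rneg <- rim_measurement(1, 10, 200, 30, mode = "scaled")
  expect_warning(out <- normalized_rim_intensity(r1, rneg), "non-positive")
  expect_true(is.na(out))
  r3 <- rim_measurement(40, 10, 70, 30, mode = "annulus")
  expect_error(normalized_rim_intensity(r1, r3), "same background mode")
})

test_that("rupture classification applies the strict 0.4 boundary and is scale-invariant", {
  expect_equal(classify_rupture(39, 100)$call, "ruptured")
  expect_equal(classify_rupture(40, 100)$call, "intact")
  expect_equal(classify_rupture(100, 100)$call, "intact")
  for (k in c(0.01, 1, 250)) {
    expect_equal(classify_rupture(39 * k, 100 * k)$call, "ruptured")
    expect_equal(classify_rupture(41 * k, 100 * k)$call, "intact")
  }
  expect_error(classify_rupture(10, 0), "positive")
})

test_that("FISH positivity requires 2x background and centromere overlap", {
  expect_true(fish_positive(2.1, 1, TRUE))
  expect_false(fish_positive(3, 1, FALSE))
  expect_true(fish_positive(2.0, 1, TRUE))     # inclusive at exactly 2x
  expect_false(fish_positive(1.9, 1, TRUE))
  expect_error(fish_positive(1, 0, TRUE), "positive")
})

test_that("inclusion rules exclude cells with more than three FISH foci", {
  r4 <- apply_inclusion_rules(4L)
  expect_false(r4$include)
  expect_match(r4$reason, "FISH foci > 3")
  expect_true(apply_inclusion_rules(2L)$include)
  r0 <- apply_inclusion_rules(0L)
  expect_true(r0$include)
  expect_true(r0$flagged)
})

test_that("chromosome count keeps only spots inside the mask", {
  sp <- voxel_spacing(100, 100, 100)
  spots <- structure(list(
    coordinates_um = rbind(c(0.2, 0.2, 0.2), c(0.2, 0.5, 0.5),
                           c(0.2, 2.0, 2.0)),
    count = 3L, threshold = 1, diameter_um = 0.2, auto_threshold = FALSE),
    class = "spot_set")
  mask <- array(FALSE, c(5, 10, 10)); mask[1:4, 1:8, 1:8] <- TRUE
  expect_equal(chromosome_count(spots, mask, sp), 2)
  empty <- structure(list(coordinates_um = matrix(numeric(0), ncol = 3),
                          count = 0L, threshold = 1, diameter_um = 0.2,
                          auto_threshold = FALSE), class = "spot_set")
  expect_equal(chromosome_count(empty, mask, sp), 0)
})
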