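test_that("phi coefficient reproduces the published validation tables", {
  expect_equal(round(phi_coefficient(nls_table()), 2), 0.87)
  expect_equal(round(phi_coefficient(nes_table()), 2), -0.85)
})

test_that("phi coefficient handles perfect association and sign conventions", {
  expect_equal(phi_coefficient(contingency_2x2(5, 0, 0, 9)), 1)
  expect_equal(phi_coefficient(contingency_2x2(1, 0, 0, 1)), 1)
  t0 <- contingency_2x2(30, 12, 7, 25)
  phi0 <- phi_coefficient(t0)
  # single margin swap negates, double swap restores
  expect_equal(phi_coefficient(contingency_2x2(12, 30, 25, 7)), -phi0)
  expect_equal(phi_coefficient(contingency_2x2(25, 7, 12, 30)), phi0)
  expect_error(phi_coefficient(contingency_2x2(3, 4, 0, 0)), "marginal")
})

test_that("Barnard's exact test: null table, published table, p-value range", {
  expect_equal(barnard_exact(contingency_2x2(1, 1, 1, 1))$p_value, 1)
  res <- barnard_exact(nls_table())
  expect_lt(res$p_value, 1e-4)
  expect_gt(res$p_value, 0)
  res2 <- barnard_exact(contingency_2x2(8, 2, 3, 7))
  expect_true(res2$p_value > 0 && res2$p_value <= 1)
})

test_that("Barnard's exact test agrees with brute-force enumeration on small tables", {
  cases <- list(c(3, 1, 0, 4), c(2, 2, 2, 2), c(4, 0, 1, 3),
                c(1, 3, 4, 1), c(5, 0, 0, 5), c(2, 3, 4, 0))
  for (cc in cases) {
    p_impl <- barnard_exact(contingency_2x2(cc[1], cc[2], cc[3], cc[4]),
                            refine = FALSE)$p_value
    p_oracle <- barnard_bruteforce(cc[1], cc[2], cc[3], cc[4])
    expect_equal(p_impl, p_oracle, tolerance = 1e-10,
                 label = paste("table", paste(cc, collapse = ",")))
  }
})

test_that("barnard_pvalue_table matches barnard_exact per table", {
  pt <- barnard_pvalue_table(5, 4)
  for (x1 in c(0L, 2L, 5L)) for (x2 in c(0L, 3L)) {
    expect_equal(pt[x1 + 1, x2 + 1],
                 barnard_exact(contingency_2x2(x1, 5 - x1, x2, 4 - x2),
                               refine = FALSE)$p_value,
                 tolerance = 1e-12)
  }
})

test_that("chi-square family test computes Pearson statistic and flags", {
  r0 <- chi_square_family(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r1 <- chi_square_family(rbind(c(20, 5), c(5, 20)))
  expect_equal(r1$statistic, 18)
  expect_equal(r1$df, 1)
  # zero cell: flagged invalid per the published policy
  rz <- chi_square_family(rbind(c(10, 0), c(5, 7)))
  expect_false(rz$valid)
  # small expected counts flagged
  rs <- chi_square_family(rbind(c(2, 1), c(1, 2)))
  expect_true(rs$small_expected)
  expect_error(chi_square_family(rbind(c(0, 0), c(0, 0))))
})

test_that("hierarchical comparison gates pairwise tests on the family test", {
  same <- rbind(a = c(10, 10), b = c(10, 10), c = c(10, 10))
  r <- hierarchical_compare(same)
  expect_equal(r$family$p_value, 1)
  expect_null(r$pairwise)

  diff <- rbind(a = c(40, 160), b = c(100, 100), c = c(160, 40))
  r2 <- hierarchical_compare(diff)
  expect_lt(r2$family$p_value, 0.05)
  expect_s3_class(r2$pairwise, "data.frame")
  expect_equal(nrow(r2$pairwise), 3)
  expect_true(all(r2$pairwise$p_adjusted >= r2$pairwise$p_raw))
  # the extreme pair carries the smallest adjusted p
  ext <- r2$pairwise$group1 == "a" & r2$pairwise$group2 == "c"
  expect_equal(which.min(r2$pairwise$p_adjusted), which(ext))
})

test_that("continuous path selects ANOVA vs Kruskal-Wallis by Shapiro-Wilk", {
  set.seed(11)
  normal <- list(a = rnorm(30), b = rnorm(30, 2), c = rnorm(30))
  rn <- hierarchical_compare(normal)
  expect_equal(rn$branch, "anova")
  expect_lt(rn$family$p_value, 0.05)
  heavy <- list(a = rcauchy(30), b = rcauchy(30), c = rcauchy(30))
  rh <- hierarchical_compare(heavy)
  expect_equal(rh$branch, "kruskal-wallis")
  expect_error(hierarchical_compare(list(a = 1:2, b = 1:5)), "at least 3")
})

test_that("Spearman rank correlation handles monotone, hand-ranked and degenerate input", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman_rho(1:7, 7:1), -1)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("chi-square power: null size, monotonicity, closed form", {
  expect_equal(chisq_power(0, 200, df = 1), 0.05)
  expect_equal(chisq_power(0, 200, df = 3, alpha = 0.1), 0.1)
  pw <- vapply(c(50, 100, 400, 1600), chisq_power, 0, effect_w = 0.2, df = 2)
  expect_true(all(diff(pw) > 0))
  expect_gt(chisq_power(0.3, 5000, df = 1), 0.999)
})

test_that("chi-square power matches a Monte-Carlo oracle", {
  # two-cell goodness-of-fit, df = 1: offset d gives w = 2d. N is large
  # enough that binomial discreteness (which biases the realized test level
  # at small N) is negligible relative to the tolerance.
  w <- 0.1; N <- 1000; d <- w / 2
  set.seed(42)
  x <- rbinom(1e5, N, 0.5 + d)
  stat <- (x - N / 2)^2 / (N / 2) + ((N - x) - N / 2)^2 / (N / 2)
  mc <- mean(stat > qchisq(0.95, 1))
  expect_equal(chisq_power(w, N, df = 1), mc, tolerance = 0.01)
})
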