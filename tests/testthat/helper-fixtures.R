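# Shared fixtures built in code.

# Reconstructed published validation tables (group sizes x percentages,
# nearest-integer): NLS-marker and NES-marker vs H3K27ac state.
nls_table <- function() contingency_2x2(183, 10, 9, 107)
nes_table <- function() contingency_2x2(18, 119, 115, 2)

# Brute-force unconditional exact p-value: direct double loop over all
# binomial outcome pairs, no shared code with barnard_exact's vectorized
# tail computation.
barnard_bruteforce <- function(n11, n12, n21, n22, n_grid = 1001L) {
  n1 <- n11 + n12; n2 <- n21 + n22
  stat <- function(x1, x2) {
    pp <- (x1 + x2) / (n1 + n2)
    v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
    if (v <= 0) return(0)
    (x1 / n1 - x2 / n2) / sqrt(v)
  }
  t_obs <- abs(stat(n11, n21))
  grid <- seq(1 / (n_grid + 1), n_grid / (n_grid + 1), length.out = n_grid)
  pmax_val <- 0
  for (pi in grid) {
    tot <- 0
    for (x1 in 0:n1) for (x2 in 0:n2) {
      if (abs(stat(x1, x2)) >= t_obs - 1e-12)
        tot <- tot + dbinom(x1, n1, pi) * dbinom(x2, n2, pi)
    }
    if (tot > pmax_val) pmax_val <- tot
  }
  min(1, pmax_val)
}

# quick small synthetic MN spec (smaller shell -> faster rendering)
small_mn_spec <- function(...) {
  synthetic_mn_spec(semi_axes_um = c(0.8, 0.75, 0.55), ...)
}
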