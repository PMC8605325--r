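#' 2x2 contingency table for binary association statistics
#'
#' Rows are the predictor (positive level first), columns the outcome
#' (positive level first). Callers must orient tables; the sign of the phi
#' coefficient depends on it.
#'
#' @param n11,n12,n21,n22 Non-negative integer cell counts
#'   (`n11` = predictor+/outcome+, `n12` = predictor+/outcome-, ...).
#' @return Object of class `contingency_2x2`.
#' @examples
#' contingency_2x2(183, 10, 9, 107)
#' @export
contingency_2x2 <- function(n11, n12, n21, n22) {
  cells <- c(n11, n12, n21, n22)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) == 0) stop("table total must be positive")
  structure(list(n11 = as.integer(n11), n12 = as.integer(n12),
                 n21 = as.integer(n21), n22 = as.integer(n22)),
            class = "contingency_2x2")
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$n11, x$n21, x$n12, x$n22), 2, 2,
         dimnames = list(predictor = c("pos", "neg"),
                         outcome = c("pos", "neg")))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(as.matrix(x)); invisible(x)
}

.as_table_2x2 <- function(t) {
  if (inherits(t, "contingency_2x2")) return(t)
  m <- as.matrix(t)
  stopifnot(all(dim(m) == c(2L, 2L)))
  contingency_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
}

# Pooled-variance score (Wald) statistic for all tables with row totals
# (n1, n2): T[x1+1, x2+1] = (x1/n1 - x2/n2) / sqrt(pp(1-pp)(1/n1+1/n2)),
# pp pooled; 0 when the pooled variance vanishes.
.barnard_stat_matrix <- function(n1, n2) {
  x1 <- 0:n1; x2 <- 0:n2
  p1 <- outer(x1 / n1, rep(1, n2 + 1L))
  p2 <- outer(rep(1, n1 + 1L), x2 / n2)
  pp <- outer(x1, x2, `+`) / (n1 + n2)
  v <- pp * (1 - pp) * (1 / n1 + 1 / n2)
  tmat <- (p1 - p2) / sqrt(v)
  tmat[v <= 0] <- 0
  tmat
}

# Null probability of the extreme set at nuisance probability pi.
.barnard_tail <- function(pi, n1, n2, extreme) {
  a <- stats::dbinom(0:n1, n1, pi)
  b <- stats::dbinom(0:n2, n2, pi)
  sum(a * (extreme %*% b))
}

#' Barnard's unconditional exact test for a 2x2 table
#'
#' Exact unconditional test on two independent binomials (fixed row totals).
#' The ordering statistic is the pooled-variance score statistic; the p-value
#' maximizes the null probability of the extreme set over the nuisance
#' success probability on a 1001-point grid followed by golden-section
#' refinement around the grid maximum.
#'
#' @param t A [contingency_2x2()] or 2x2 matrix (rows = groups).
#' @param alternative `"two.sided"` (|T| ordering), `"greater"` or `"less"`
#'   (signed ordering; `"greater"` tests p1 > p2).
#' @param n_grid Nuisance-parameter grid size.
#' @param refine Refine the grid maximum with [stats::optimize()].
#' @return List of class `mn_test_result`: `statistic` (score statistic of
#'   the observed table), `p_value`, `method`, `nuisance_pi` (maximizer).
#' @examples
#' barnard_exact(contingency_2x2(183, 10, 9, 107))
#' @export
barnard_exact <- function(t, alternative = c("two.sided", "greater", "less"),
                          n_grid = 1001L, refine = TRUE) {
  alternative <- match.arg(alternative)
  t <- .as_table_2x2(t)
  n1 <- t$n11 + t$n12; n2 <- t$n21 + t$n22
  if (n1 == 0L || n2 == 0L) stop("both row totals must be positive")
  tmat <- .barnard_stat_matrix(n1, n2)
  t_obs <- tmat[t$n11 + 1L, t$n21 + 1L]
  eps <- 1e-12
  extreme <- switch(alternative,
    two.sided = abs(tmat) >= abs(t_obs) - eps,
    greater   = tmat >= t_obs - eps,
    less      = tmat <= t_obs + eps)
  storage.mode(extreme) <- "double"
  grid <- seq(1 / (n_grid + 1), n_grid / (n_grid + 1), length.out = n_grid)
  vals <- vapply(grid, .barnard_tail, 0, n1 = n1, n2 = n2, extreme = extreme)
  i <- which.max(vals)
  p <- vals[i]
  pi_star <- grid[i]
  if (refine) {
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
    opt <- stats::optimize(.barnard_tail, c(lo, hi), maximum = TRUE,
                           n1 = n1, n2 = n2, extreme = extreme,
                           tol = .Machine$double.eps^0.5)
    if (opt$objective > p) { p <- opt$objective; pi_star <- opt$maximum }
  }
  structure(list(statistic = t_obs, p_value = min(1, p), df = NA_real_,
                 method = sprintf("Barnard unconditional exact test (%s)", alternative),
                 nuisance_pi = pi_star, adjusted = FALSE),
            class = "mn_test_result")
}

#' @export
print.mn_test_result <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %.6g, p = %.6g%s\n", x$statistic, x$p_value,
              if (isTRUE(x$adjusted)) " (adjusted)" else ""))
  invisible(x)
}

#' Barnard p-values for every table at fixed row totals
#'
#' Computes the two-sided unconditional p-value for all
#' `(n1 + 1) * (n2 + 1)` possible tables at once (grid maximization shared
#' across tables via a single cumulative sum per nuisance value). Used for
#' type-I-error simulations where [barnard_exact()] per draw would be
#' wasteful.
#'
#' @param n1,n2 Row totals.
#' @param n_grid Nuisance grid size.
#' @param refine Golden-section refinement per distinct statistic value.
#' @return Matrix `p[x1 + 1, x2 + 1]` of p-values.
#' @export
barnard_pvalue_table <- function(n1, n2, n_grid = 1001L, refine = FALSE) {
  tmat <- .barnard_stat_matrix(n1, n2)
  # round so that exactly tied statistics (symmetric tables) group together
  # despite ~1e-16 floating error
  ta <- round(abs(as.vector(tmat)), 10)
  ord <- order(ta, decreasing = TRUE)
  u <- unique(ta[ord])                    # distinct |T|, descending
  grp <- match(ta, u)                     # group id per table
  # last position (in sorted order) belonging to each group
  grp_sorted <- grp[ord]
  boundary <- vapply(seq_along(u), function(g) max(which(grp_sorted == g)), 0L)
  grid <- seq(1 / (n_grid + 1), n_grid / (n_grid + 1), length.out = n_grid)
  pmax_grp <- rep(0, length(u))
  for (pi in grid) {
    probs <- as.vector(outer(stats::dbinom(0:n1, n1, pi),
                             stats::dbinom(0:n2, n2, pi)))
    cp <- cumsum(probs[ord])
    pg <- cp[boundary]
    pmax_grp <- pmax(pmax_grp, pg)
  }
  if (refine) {
    for (g in seq_along(u)) {
      extreme <- matrix(as.double(abs(tmat) >= u[g] - 1e-12),
                        nrow = n1 + 1L)
      opt <- stats::optimize(.barnard_tail, c(0, 1), maximum = TRUE,
                             n1 = n1, n2 = n2, extreme = extreme)
      pmax_grp[g] <- max(pmax_grp[g], opt$objective)
    }
  }
  matrix(pmin(1, pmax_grp[grp]), nrow = n1 + 1L)
}

#' Phi (mean squared contingency) coefficient of a 2x2 table
#'
#' `phi = (n11 n22 - n12 n21) / sqrt(r1 r2 c1 c2)` with row and column
#' totals in the denominator; the Pearson correlation of the two binary
#' variables. Sign depends on table orientation (rows = predictor, positive
#' level first); swapping one margin negates it.
#'
#' @param t A [contingency_2x2()] or 2x2 matrix.
#' @return Value in `[-1, 1]`.
#' @examples
#' phi_coefficient(contingency_2x2(183, 10, 9, 107))  # 0.87
#' @export
phi_coefficient <- function(t) {
  t <- .as_table_2x2(t)
  r1 <- t$n11 + t$n12; r2 <- t$n21 + t$n22
  c1 <- t$n11 + t$n21; c2 <- t$n12 + t$n22
  if (any(c(r1, r2, c1, c2) == 0))
    stop("phi coefficient undefined: a marginal total is zero")
  (as.numeric(t$n11) * t$n22 - as.numeric(t$n12) * t$n21) /
    sqrt(as.numeric(r1) * r2 * c1 * c2)
}

#' Chi-square family test on a k x 2 count table
#'
#' Pearson chi-square over k groups of binary outcomes, used as the family
#' gate before any pairwise testing. Following the published policy, the
#' test is flagged invalid when the table contains a zero count and flagged
#' with a warning when more than one expected count falls below 5.
#'
#' @param counts k x 2 matrix (rows = groups, columns = outcome +/-).
#' @return `mn_test_result` with `statistic`, `df`, `p_value`, `valid`
#'   (FALSE when a zero cell makes the family test inapplicable) and
#'   `small_expected` flag.
#' @export
chi_square_family <- function(counts) {
  m <- as.matrix(counts)
  if (ncol(m) != 2L || nrow(m) < 2L) stop("counts must be a k x 2 matrix, k >= 2")
  if (sum(m) == 0) stop("table grand total is zero")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) stop("a margin of the table is zero")
  stat <- sum((m - expected)^2 / expected)
  df <- nrow(m) - 1L
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p,
                 method = "Pearson chi-square family test",
                 valid = !any(m == 0),
                 small_expected = sum(expected < 5) > 1,
                 adjusted = FALSE),
            class = "mn_test_result")
}

#' Family-gated hierarchical group comparison
#'
#' The published testing policy: for three or more groups a family test is
#' run first (chi-square for categorical counts; one-way ANOVA or
#' Kruskal-Wallis for continuous observations, chosen by per-group
#' Shapiro-Wilk normality); pairwise comparisons (Barnard's exact test for
#' counts, Bonferroni-corrected t or Wilcoxon tests for continuous data) are
#' emitted only when the family test rejects at `alpha`.
#'
#' @param groups Either a k x 2 count matrix (categorical path) or a named
#'   list of numeric vectors (continuous path, each of length >= 3).
#' @param alpha Family-gate significance level.
#' @return List with `family` (`mn_test_result`), `branch`
#'   (`"chi-square"`, `"anova"` or `"kruskal-wallis"`), and `pairwise`
#'   (data.frame of group pairs with raw and Bonferroni-adjusted p, or NULL
#'   when the family test does not reject).
#' @export
hierarchical_compare <- function(groups, alpha = 0.05) {
  if (is.matrix(groups) || is.data.frame(groups)) {
    m <- as.matrix(groups)
    if (is.null(rownames(m))) rownames(m) <- paste0("group", seq_len(nrow(m)))
    fam <- chi_square_family(m)
    branch <- "chi-square"
    pairwise <- NULL
    if (fam$p_value < alpha) {
      pairs <- utils::combn(nrow(m), 2)
      res <- apply(pairs, 2, function(ij) {
        bt <- barnard_exact(m[ij, , drop = FALSE])
        c(p = bt$p_value, stat = bt$statistic)
      })
      pairwise <- data.frame(
        group1 = rownames(m)[pairs[1, ]], group2 = rownames(m)[pairs[2, ]],
        method = "Barnard exact", statistic = res["stat", ],
        p_raw = res["p", ],
        p_adjusted = stats::p.adjust(res["p", ], method = "bonferroni"),
        stringsAsFactors = FALSE)
    }
    return(list(family = fam, branch = branch, pairwise = pairwise))
  }

  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  if (any(lengths(groups) < 3L))
    stop("each continuous group must have at least 3 observations")
  normal <- vapply(groups, function(g) stats::shapiro.test(g)$p.value, 0) > alpha
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (all(normal)) {
    branch <- "anova"
    fit <- stats::aov(values ~ fac)
    tab <- summary(fit)[[1]]
    fam <- structure(list(statistic = tab$`F value`[1], df = tab$Df[1],
                          p_value = tab$`Pr(>F)`[1],
                          method = "one-way ANOVA family test",
                          adjusted = FALSE), class = "mn_test_result")
  } else {
    branch <- "kruskal-wallis"
    kw <- stats::kruskal.test(values, fac)
    fam <- structure(list(statistic = unname(kw$statistic),
                          df = unname(kw$parameter), p_value = kw$p.value,
                          method = "Kruskal-Wallis family test",
                          adjusted = FALSE), class = "mn_test_result")
  }
  pairwise <- NULL
  if (fam$p_value < alpha) {
    pairs <- utils::combn(length(groups), 2)
    praw <- apply(pairs, 2, function(ij) {
      a <- groups[[ij[1]]]; b <- groups[[ij[2]]]
      if (branch == "anova") stats::t.test(a, b)$p.value
      else stats::wilcox.test(a, b, exact = FALSE)$p.value
    })
    pairwise <- data.frame(
      group1 = names(groups)[pairs[1, ]], group2 = names(groups)[pairs[2, ]],
      method = if (branch == "anova") "Welch t" else "Wilcoxon",
      statistic = NA_real_, p_raw = praw,
      p_adjusted = stats::p.adjust(praw, method = "bonferroni"),
      stringsAsFactors = FALSE)
  }
  list(family = fam, branch = branch, pairwise = pairwise)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); used for
#' monotone relationships between non-normal variables such as MN area vs
#' volume.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_rho undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Post-hoc power of a chi-square test
#'
#' `power = P(chisq'(df, ncp = N w^2) > q)` with `q` the upper-alpha critical
#' value of the central chi-square: the standard noncentral formulation with
#' Cohen's effect size `w`.
#'
#' @param effect_w Cohen's w (>= 0).
#' @param N_total Total sample size.
#' @param df Degrees of freedom.
#' @param alpha Significance level.
#' @return Power in `[0, 1]`.
#' @examples
#' chisq_power(0.3, 100, df = 1)
#' @export
chisq_power <- function(effect_w, N_total, df, alpha = 0.05) {
  stopifnot(effect_w >= 0, N_total >= 1, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = N_total * effect_w^2, lower.tail = FALSE)
}
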