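#' Minimum-volume enclosing ellipsoid (Khachiyan iteration)
#'
#' Fits the smallest ellipsoid `(x - c)' A (x - c) <= 1` containing all
#' points, by the Khachiyan barycentric-coordinate ascent. Used for the
#' "inner" MN volume from lamin-positive voxel coordinates.
#'
#' @param points n x 3 matrix of coordinates (um), n >= 4 and affinely
#'   independent.
#' @param tolerance Relative convergence tolerance on the barycentric
#'   optimality gap.
#' @param max_iter Iteration cap.
#' @return List with `center` (length 3), `A` (3 x 3 shape matrix),
#'   `semi_axes` (descending), `volume_um3`, `max_violation`
#'   (max of `(x-c)'A(x-c) - 1` over the input; <= O(tolerance)).
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' fit_enclosing_ellipsoid(cube)$volume_um3  # ~ pi * sqrt(3) / 2
#' @export
fit_enclosing_ellipsoid <- function(points, tolerance = 1e-6,
                                    max_iter = 200000L) {
  P <- unique(as.matrix(points))
  storage.mode(P) <- "double"
  # the MVEE touches only convex-hull vertices; reduce large voxel clouds
  # to per-slice 2D hull vertices first (exact reduction)
  if (nrow(P) > 1500L && ncol(P) == 3L) {
    keep <- unlist(lapply(split(seq_len(nrow(P)), P[, 1]), function(idx) {
      if (length(idx) < 4L) return(idx)
      idx[grDevices::chull(P[idx, 2], P[idx, 3])]
    }))
    P <- P[sort(unique(keep)), , drop = FALSE]
  }
  d <- ncol(P); n <- nrow(P)
  if (d != 3L) stop("points must have 3 columns")
  if (n < 4L) stop("need at least 4 distinct points")
  ctr <- colMeans(P)
  if (qr(sweep(P, 2, ctr))$rank < 3L)
    stop("degenerate input: points are affinely dependent (coplanar/collinear)")
  Q <- t(cbind(P, 1))                       # (d+1) x n
  u <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    X <- Q %*% (u * t(Q))                   # (d+1) x (d+1)
    M <- colSums(solve(X, Q) * Q)           # Mahalanobis-type scores
    j <- which.max(M)
    eps_gap <- M[j] / (d + 1) - 1
    if (eps_gap < tolerance) break
    step <- (M[j] - d - 1) / ((d + 1) * (M[j] - 1))
    u <- (1 - step) * u
    u[j] <- u[j] + step
  }
  c0 <- drop(crossprod(P, u))
  A <- solve(crossprod(P, u * P) - tcrossprod(c0)) / d
  A <- (A + t(A)) / 2
  q <- rowSums((sweep(P, 2, c0) %*% A) * sweep(P, 2, c0))
  ev <- eigen(A, symmetric = TRUE)$values
  if (any(ev <= 0)) stop("degenerate ellipsoid fit")
  semi <- sort(1 / sqrt(ev), decreasing = TRUE)
  list(center = c0, A = A, semi_axes = semi,
       volume_um3 = 4 * pi / 3 * prod(semi),
       max_violation = max(q) - 1, iterations = it)
}

# Incremental (beneath-beyond) 3D convex hull. Faces are kept as an F x 3
# index matrix with outward normals in an F x 3 matrix so the per-point
# visibility test is one matrix product.
.convex_hull_3d <- function(P, eps_rel = 1e-10) {
  n <- nrow(P)
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  eps <- eps_rel * scale
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])

  # initial simplex: extreme pair, then max area, then max volume
  i1 <- which.min(P[, 1])
  i2 <- which.max(rowSums(sweep(P, 2, P[i1, ])^2))
  ab <- P[i2, ] - P[i1, ]
  Pc <- sweep(P, 2, P[i1, ])
  crx <- cbind(ab[2] * Pc[, 3] - ab[3] * Pc[, 2],
               ab[3] * Pc[, 1] - ab[1] * Pc[, 3],
               ab[1] * Pc[, 2] - ab[2] * Pc[, 1])
  i3 <- which.max(rowSums(crx^2))
  nrm0 <- cr(ab, P[i3, ] - P[i1, ])
  d3 <- abs(drop(Pc %*% nrm0))
  i4 <- which.max(d3)
  if (d3[i4] <= eps * sqrt(sum(nrm0^2)))
    stop("degenerate input: points are coplanar")
  init <- c(i1, i2, i3, i4)
  centroid <- colMeans(P[init, ])

  mk_face <- function(f) {
    a <- P[f[1], ]; nn <- cr(P[f[2], ] - a, P[f[3], ] - a)
    if (sum(nn * (centroid - a)) > 0) { f <- f[c(1, 3, 2)]; nn <- -nn }
    list(f = f, n = nn, o = sum(nn * P[f[1], ]), l = sqrt(sum(nn^2)))
  }
  fs <- lapply(list(init[c(1, 2, 3)], init[c(1, 2, 4)],
                    init[c(1, 3, 4)], init[c(2, 3, 4)]), mk_face)
  faces <- do.call(rbind, lapply(fs, `[[`, "f"))
  nrm <- do.call(rbind, lapply(fs, `[[`, "n"))
  off <- vapply(fs, `[[`, 0, "o")
  nl <- vapply(fs, `[[`, 0, "l")

  for (p in setdiff(seq_len(n), init)) {
    x <- P[p, ]
    vis <- drop(nrm %*% x) - off > eps * nl
    if (!any(vis)) next
    vf <- faces[vis, , drop = FALSE]
    edges <- rbind(vf[, 1:2], vf[, 2:3], vf[, c(3, 1)])
    key <- pmin(edges[, 1], edges[, 2]) * (n + 1) +
      pmax(edges[, 1], edges[, 2])
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    keep <- !vis
    faces <- faces[keep, , drop = FALSE]
    nrm <- nrm[keep, , drop = FALSE]
    off <- off[keep]; nl <- nl[keep]
    for (e in seq_len(nrow(horizon))) {
      nf <- mk_face(c(horizon[e, 1], horizon[e, 2], p))
      faces <- rbind(faces, nf$f)
      nrm <- rbind(nrm, nf$n)
      off <- c(off, nf$o); nl <- c(nl, nf$l)
    }
  }
  list(points = P, faces = lapply(seq_len(nrow(faces)),
                                  function(i) faces[i, ]))
}

#' Volume of the 3D convex hull of a point set
#'
#' Builds the hull incrementally and sums signed tetrahedra against the
#' centroid. Used for the "outer" MN volume from lamin-positive voxels.
#'
#' @param points n x 3 matrix (um); n >= 4, not all coplanar.
#' @param reduce For large inputs, pre-reduce to per-z-slice 2D hull
#'   vertices (exact: interior points never contribute to the hull).
#' @return Hull volume (um^3).
#' @examples
#' convex_hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1)))  # 1
#' @export
convex_hull_volume <- function(points, reduce = TRUE) {
  P <- unique(as.matrix(points))
  storage.mode(P) <- "double"
  if (ncol(P) != 3L) stop("points must have 3 columns")
  if (nrow(P) < 4L) stop("need at least 4 distinct points")
  if (reduce && nrow(P) > 2000L) {
    keep <- unlist(lapply(split(seq_len(nrow(P)), P[, 1]), function(idx) {
      if (length(idx) < 4L) return(idx)
      idx[grDevices::chull(P[idx, 2], P[idx, 3])]
    }))
    P <- P[sort(unique(keep)), , drop = FALSE]
  }
  hull <- .convex_hull_3d(P)
  o <- colMeans(P)
  vol <- 0
  for (f in hull$faces) {
    a <- hull$points[f[1], ] - o
    b <- hull$points[f[2], ] - o
    c3 <- hull$points[f[3], ] - o
    vol <- vol + (a[1] * (b[2] * c3[3] - b[3] * c3[2]) -
                  a[2] * (b[1] * c3[3] - b[3] * c3[1]) +
                  a[3] * (b[1] * c3[2] - b[2] * c3[1])) / 6
  }
  unname(abs(vol))
}
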