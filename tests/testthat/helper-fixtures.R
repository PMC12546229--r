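# Shared fixtures and independent brute-force oracles. Everything is built
# in code; no files on disk.

# Regular grid on a cylinder surface (optionally noisy), axis through
# `base` along unit `dir`.
cyl_points <- function(radius = 0.03, len = 0.5, base = c(0, 0, 0),
                       dir = c(0, 0, 1), spacing = 0.005, sigma = 0,
                       half = FALSE, seed = NULL) {
  dir <- dir / sqrt(sum(dir^2))
  b <- treereg:::.plane_basis(dir)
  s <- seq(0, len, by = spacing)
  nc <- max(8, ceiling(2 * pi * radius / spacing))
  ang <- seq(0, 2 * pi, length.out = nc + 1)[-(nc + 1)]
  if (half) ang <- ang[ang < pi]
  g <- expand.grid(s = s, a = ang)
  P <- matrix(base, nrow(g), 3, byrow = TRUE) + outer(g$s, dir) +
    radius * (outer(cos(g$a), b$e1) + outer(sin(g$a), b$e2))
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    P <- P + matrix(rnorm(length(P), sd = sigma), ncol = 3)
  }
  P
}

# O(N^2) mean distance to the k nearest neighbors (SOR oracle).
bf_knn_mean <- function(P, k) {
  D <- as.matrix(dist(P))
  diag(D) <- Inf
  apply(D, 1, function(r) mean(sort(r)[seq_len(k)]))
}

# Union-find connected components under a distance tolerance
# (clustering oracle).
bf_clusters <- function(P, tol) {
  n <- nrow(P)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  D <- as.matrix(dist(P))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) if (D[i, j] <= tol) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), roots))
}

# Brute-force nearest neighbor of each row of Q in X.
bf_nn <- function(Q, X) {
  t(vapply(seq_len(nrow(Q)), function(i) {
    d2 <- colSums((t(X) - Q[i, ])^2)
    j <- which.min(d2)
    c(j, sqrt(d2[j]))
  }, c(0, 0)))
}

# Rotation matrix from axis + angle (Rodrigues oracle).
rodrigues_R <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Small, fast synthetic tree + opposed scan pair; coarser sampling keeps
# the suite quick while the post-voxel (8 mm) geometry is unchanged.
quick_spec <- function(seed = 1, ...) {
  tree_spec(surface_sampling = 0.005, seed = seed, ...)
}

quick_pair <- function(seed = 1, ...) {
  tree <- generate_tree(quick_spec(seed))
  simulate_two_stations(tree, seed = seed, ...)
}

expect_transform_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(unclass(a) - unclass(b))), tol)
}
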