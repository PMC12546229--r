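# Geometric kernel: seeded RANSAC cylinder fitting (two points + PCA
# normals, Levenberg-Marquardt refinement), Euclidean clustering, XOY axis
# projection and 2D line intersection.

#' Cylinder primitive
#'
#' Axis (point + unit direction), radius, and the inlier set of the cloud it
#' was fitted to. The workhorse primitive for trunks and branch stubs.
#'
#' @param axis_point 3D point on the axis (m).
#' @param axis_dir unit 3-vector.
#' @param radius cylinder radius (m), positive.
#' @param inlier_idx integer indices into the fitted cloud.
#' @param n_fitted size of the fitted cloud (for the inlier ratio).
#' @return An object of class `cylinder3d`.
#' @export
cylinder3d <- function(axis_point, axis_dir, radius, inlier_idx = integer(),
                       n_fitted = NA_integer_) {
  if (radius <= 0) stop_treereg("cylinder radius must be positive", "treereg_input_error")
  structure(list(axis_point = as.numeric(axis_point),
                 axis_dir = unit_vec(as.numeric(axis_dir)),
                 radius = as.numeric(radius),
                 inlier_idx = as.integer(inlier_idx),
                 inlier_ratio = if (is.na(n_fitted)) NA_real_
                                else length(inlier_idx) / n_fitted),
            class = "cylinder3d")
}

#' @export
print.cylinder3d <- function(x, ...) {
  cat(sprintf("<cylinder3d: r = %.4f m, axis (%.3f, %.3f, %.3f), %d inliers (%.0f%%)>\n",
              x$radius, x$axis_dir[1], x$axis_dir[2], x$axis_dir[3],
              length(x$inlier_idx), 100 * x$inlier_ratio))
  invisible(x)
}

# Orthonormal basis of the plane orthogonal to d.
.plane_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit_vec(pracma_cross(ref, d))
  e2 <- pracma_cross(d, e1)
  list(e1 = e1, e2 = e2)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Levenberg-Marquardt refinement of (axis point, axis dir) on a fixed point
# set; the radius is profiled out as the mean radial distance.
.refine_cylinder <- function(P, a0, d0) {
  basis <- .plane_basis(d0)
  resid <- function(p) {
    a <- a0 + p[1] * basis$e1 + p[2] * basis$e2
    d <- unit_vec(d0 + p[3] * basis$e1 + p[4] * basis$e2)
    dist <- point_line_dist(P, a, d)
    dist - mean(dist)
  }
  fit <- minpack.lm::nls.lm(par = rep(0, 4), fn = resid,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  a <- a0 + p[1] * basis$e1 + p[2] * basis$e2
  d <- unit_vec(d0 + p[3] * basis$e1 + p[4] * basis$e2)
  r <- mean(point_line_dist(P, a, d))
  list(axis_point = a, axis_dir = d, radius = r)
}

#' RANSAC cylinder fit
#'
#' Candidate models are generated from two sampled points plus their PCA
#' surface normals (10-nearest-neighbor neighborhoods): the axis direction
#' is the normalized cross product of the normals and the axis point the
#' intersection of the two normal lines in the plane orthogonal to it.
#' Inliers satisfy `| radial distance - radius | <= dist_thresh`. The best
#' hypothesis is refined by nonlinear least squares on its inliers (two
#' rounds, radius profiled as the mean radial distance) and the axis is
#' canonicalized to a positive dot product with `axis_prior` (or +z).
#'
#' @param cloud a [point_cloud()] with at least 6 points.
#' @param dist_thresh inlier surface-distance threshold (m).
#' @param n_iter number of sampled hypotheses.
#' @param seed RNG seed; the fit is bit-reproducible for a fixed seed.
#' @param axis_prior optional unit 3-vector; hypotheses whose axis deviates
#'   from it by more than `max_axis_dev` are rejected.
#' @param max_axis_dev maximum axis deviation from the prior (radians).
#' @param radius_bounds plausible radius interval (m) for hypotheses.
#' @return A [cylinder3d()] with `inlier_idx` into `cloud`.
#' @export
ransac_cylinder <- function(cloud, dist_thresh = 0.004, n_iter = 5000, seed = 0,
                            axis_prior = NULL, max_axis_dev = deg2rad(10),
                            radius_bounds = c(0.002, 0.25)) {
  P <- cloud$points
  n <- nrow(P)
  if (n < 6)
    stop_treereg("cylinder fit needs at least 6 points", "treereg_degenerate_error")
  k <- min(10L, n - 1L)
  Nrm <- cpp_pca_normals(P, k)
  pairs <- with_seed(seed, matrix(sample.int(n, 2L * n_iter, replace = TRUE), ncol = 2))
  prior <- if (is.null(axis_prior)) numeric(0) else unit_vec(as.numeric(axis_prior))
  cand <- cpp_ransac_cylinder(P, Nrm, pairs, dist_thresh, prior,
                              if (is.null(axis_prior)) 0 else cos(max_axis_dev),
                              radius_bounds[1], radius_bounds[2])
  if (cand$count < 6)
    stop_treereg("cylinder fit failed: no hypothesis satisfied the constraints",
                 "treereg_fit_error")
  a <- as.numeric(cand$axis_point)
  d <- unit_vec(as.numeric(cand$axis_dir))
  r <- cand$radius
  for (round in 1:2) {
    inl <- which(abs(point_line_dist(P, a, d) - r) <= dist_thresh)
    if (length(inl) < 6) break
    ref <- .refine_cylinder(P[inl, , drop = FALSE], a, d)
    if (ref$radius < radius_bounds[1] || ref$radius > radius_bounds[2])
      stop_treereg("cylinder fit failed: refined radius left the plausible range",
                   "treereg_fit_error")
    a <- ref$axis_point; d <- ref$axis_dir; r <- ref$radius
  }
  inl <- which(abs(point_line_dist(P, a, d) - r) <= dist_thresh)
  ref_dir <- if (is.null(axis_prior)) c(0, 0, 1) else unit_vec(axis_prior)
  dp <- sum(d * ref_dir)
  if (abs(dp) < 1e-12) {
    nz <- which(abs(d) > 1e-12)[1]
    if (d[nz] < 0) d <- -d
  } else if (dp < 0) d <- -d
  if (!is.null(axis_prior) && acos(clamp(abs(sum(d * ref_dir)), 0, 1)) > max_axis_dev)
    stop_treereg("cylinder fit failed: refined axis violates the prior",
                 "treereg_fit_error")
  cylinder3d(a, d, r, inlier_idx = inl, n_fitted = n)
}

#' Cluster primitive
#' @param indices integer point indices (unique).
#' @return An object of class `cluster3d` with fields `indices` and `size`.
#' @export
cluster3d <- function(indices) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop_treereg("cluster indices must be unique",
                                           "treereg_input_error")
  structure(list(indices = indices, size = length(indices)), class = "cluster3d")
}

#' Euclidean clustering
#'
#' Connected components of the graph linking points closer than `tolerance`.
#' Components smaller than `min_size` or larger than `max_size` are
#' discarded (the cluster size gate). Clusters are returned in descending
#' size order (ties by smallest member index).
#'
#' @param cloud a [point_cloud()].
#' @param tolerance connection distance (m).
#' @param min_size,max_size inclusive size gate.
#' @return A list of [cluster3d()] objects (possibly empty).
#' @export
euclidean_cluster <- function(cloud, tolerance = 0.012, min_size = 1,
                              max_size = Inf) {
  if (tolerance <= 0) stop_treereg("tolerance must be positive", "treereg_input_error")
  n <- n_points(cloud)
  if (n == 0) return(list())
  comp <- cpp_radius_cluster(cloud$points, tolerance)
  groups <- split(seq_len(n), comp)
  sizes <- lengths(groups)
  keep <- sizes >= min_size & sizes <= max_size
  groups <- groups[keep]
  if (length(groups) == 0) return(list())
  ord <- order(-lengths(groups), vapply(groups, min, 1L))
  unname(lapply(groups[ord], cluster3d))
}

#' 2D line (XOY plane)
#' @param point length-2 point on the line.
#' @param dir direction (normalized internally).
#' @return An object of class `line2d`.
#' @export
line2d <- function(point, dir) {
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-12) stop_treereg("2D line direction must be non-null",
                                "treereg_degenerate_error")
  structure(list(point = as.numeric(point)[1:2], dir = as.numeric(dir)[1:2] / nrm),
            class = "line2d")
}

#' Project a cylinder axis onto the XOY plane
#'
#' @param cyl a [cylinder3d()]; its axis must deviate from vertical by more
#'   than ~1e-6 rad, otherwise the projection is degenerate.
#' @return A [line2d()] through `(axis_point.x, axis_point.y)`.
#' @export
project_axis_xoy <- function(cyl) {
  dxy <- cyl$axis_dir[1:2]
  if (sqrt(sum(dxy^2)) < 1e-6)
    stop_treereg("cannot project a vertical axis onto the XOY plane",
                 "treereg_degenerate_error")
  line2d(cyl$axis_point[1:2], dxy)
}

#' Intersection and signed angle of two 2D lines
#'
#' @param a,b [line2d()] objects; near-parallel lines (|sin| of the angle
#'   below 1e-3) raise a parallel-lines error the caller can fall back on.
#' @return A list with `O` (the intersection point) and `alpha`, the signed
#'   counter-clockwise angle in `(-pi, pi]` rotating `a$dir` onto `b$dir`.
#' @export
line_intersection_2d <- function(a, b) {
  cr <- a$dir[1] * b$dir[2] - a$dir[2] * b$dir[1]
  dt <- sum(a$dir * b$dir)
  if (abs(cr) < 1e-3)
    stop_treereg("projected axes are (near-)parallel", "treereg_parallel_lines")
  # a$point + s a$dir = b$point + t b$dir
  rhs <- b$point - a$point
  s <- (rhs[1] * b$dir[2] - rhs[2] * b$dir[1]) / cr
  O <- a$point + s * a$dir
  alpha <- atan2(cr, dt)
  if (alpha <= -pi) alpha <- alpha + 2 * pi
  list(O = O, alpha = alpha)
}
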