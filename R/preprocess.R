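# Preprocessing: ground-plane RANSAC, ground removal, statistical outlier
# removal and voxel downsampling. Heights are signed distances to the fitted
# plane; the cloud is never re-leveled, because the coarse model assumes the
# scanner's z axis is the shared vertical.

#' Ground plane
#'
#' Plane `{x : normal . x + offset = 0}` with a unit normal oriented upward
#' (positive z component).
#'
#' @param normal unit 3-vector.
#' @param offset scalar (m).
#' @param inlier_count number of RANSAC inliers supporting the fit.
#' @return An object of class `ground_plane`.
#' @export
ground_plane <- function(normal, offset, inlier_count = NA_integer_) {
  normal <- unit_vec(as.numeric(normal))
  if (normal[3] < 0) {
    normal <- -normal
    offset <- -offset
  }
  structure(list(normal = normal, offset = as.numeric(offset),
                 inlier_count = as.integer(inlier_count)),
            class = "ground_plane")
}

#' @export
print.ground_plane <- function(x, ...) {
  cat(sprintf("<ground_plane: normal (%.4f, %.4f, %.4f), offset %.4f m, %s inliers>\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset,
              ifelse(is.na(x$inlier_count), "?", x$inlier_count)))
  invisible(x)
}

#' Fit the ground plane with seeded RANSAC
#'
#' Maximizes the number of points within `dist_thresh` of a 3-point plane
#' hypothesis over `n_iter` seeded trials, then refines the winner by a
#' least-squares (total) fit on its inlier set. The normal is flipped to
#' point up.
#'
#' @param cloud a [point_cloud()] containing the ground.
#' @param dist_thresh inlier distance threshold (m).
#' @param n_iter number of RANSAC hypotheses.
#' @param seed RNG seed (the fit is bit-reproducible for a fixed seed).
#' @return A [ground_plane()].
#' @export
fit_ground_plane <- function(cloud, dist_thresh = 0.010, n_iter = 1000, seed = 0) {
  P <- cloud$points
  n <- nrow(P)
  if (n < 3)
    stop_treereg("ground plane fit needs at least 3 points", "treereg_degenerate_error")
  samples <- with_seed(seed,
    matrix(sample.int(n, 3L * n_iter, replace = TRUE), ncol = 3))
  fit <- cpp_ransac_plane(P, samples, dist_thresh)
  if (fit$count < 3)
    stop_treereg("ground plane fit failed: degenerate (collinear?) input",
                 "treereg_degenerate_error")
  d <- abs(P %*% fit$normal + fit$offset)
  inl <- which(d <= dist_thresh)
  # least-squares refit: smallest principal direction of the inlier scatter
  Q <- P[inl, , drop = FALSE]
  mu <- colMeans(Q)
  C <- crossprod(sweep(Q, 2, mu))
  ev <- eigen(C, symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300))
    stop_treereg("ground plane fit failed: inliers are collinear",
                 "treereg_degenerate_error")
  off <- -sum(nrm * mu)
  count <- sum(abs(P %*% nrm + off) <= dist_thresh)
  ground_plane(nrm, off, count)
}

#' Height of points above the ground plane
#'
#' Signed distance `normal . x + offset`, positive above ground.
#'
#' @param x a length-3 coordinate, an `n x 3` matrix, or a [point_cloud()].
#' @param plane a [ground_plane()].
#' @return Numeric vector of signed heights (m).
#' @export
height_above_ground <- function(x, plane) {
  if (inherits(x, "point_cloud")) x <- x$points
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  as.vector(x %*% plane$normal + plane$offset)
}

#' Remove ground points
#'
#' Keeps points strictly higher than `band` above the fitted plane.
#'
#' @param cloud a [point_cloud()].
#' @param plane a [ground_plane()].
#' @param band height band above the plane still treated as ground (m).
#' @return The [point_cloud()] of retained points; the number removed is
#'   attached as attribute `"n_removed"`.
#' @export
remove_ground <- function(cloud, plane, band = 0.020) {
  h <- height_above_ground(cloud, plane)
  keep <- h > band
  out <- subset_cloud(cloud, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Statistical outlier removal
#'
#' For each point, the mean distance to its `k` nearest neighbors is
#' computed; points whose mean distance exceeds `mu + std_mult * sigma`
#' (mean and standard deviation of those per-point means over the whole
#' cloud; one-sided upper cut) are removed. A second pass may remove further
#' points; the filter is not idempotent.
#'
#' @param cloud a [point_cloud()] with more than `k` points.
#' @param k neighborhood size.
#' @param std_mult standard deviation multiplier.
#' @return The filtered [point_cloud()] with attribute `"n_removed"`.
#' @export
statistical_outlier_removal <- function(cloud, k = 5, std_mult = 0.1) {
  n <- n_points(cloud)
  if (n <= k)
    stop_treereg(sprintf("statistical outlier removal needs more than k = %d points", k),
                 "treereg_degenerate_error")
  md <- cpp_knn_mean_dist(cloud$points, as.integer(k))
  cutoff <- mean(md) + std_mult * stats::sd(md)
  keep <- md <= cutoff
  out <- subset_cloud(cloud, keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Voxel-grid downsampling
#'
#' One output point per occupied voxel, at the centroid of the voxel's
#' points. The voxel index of point `x` is `floor((x - origin) / voxel)` per
#' axis, with the per-axis minimum of the cloud as origin. Labels and branch
#' ids are taken from the first point of each voxel (file order); normals are
#' averaged and renormalized.
#'
#' @param cloud a [point_cloud()].
#' @param voxel voxel edge length (m), default 8 mm.
#' @return The downsampled [point_cloud()] (one point per occupied voxel,
#'   ordered by voxel index).
#' @export
voxel_downsample <- function(cloud, voxel = 0.008) {
  if (voxel <= 0) stop_treereg("voxel size must be positive", "treereg_input_error")
  n <- n_points(cloud)
  if (n == 0) return(cloud)
  P <- cloud$points
  org <- apply(P, 2, min)
  idx <- floor(sweep(P, 2, org) / voxel)
  has_n <- !is.null(cloud$normals)
  cols <- list(ix = idx[, 1], iy = idx[, 2], iz = idx[, 3],
               x = P[, 1], y = P[, 2], z = P[, 3], ord = seq_len(n))
  if (has_n) cols <- c(cols, list(nx = cloud$normals[, 1],
                                  ny = cloud$normals[, 2],
                                  nz = cloud$normals[, 3]))
  dt <- data.table::as.data.table(cols)
  agg <- dt[, c(list(x = mean(x), y = mean(y), z = mean(z), first = ord[which.min(ord)]),
                if (has_n) list(nx = mean(nx), ny = mean(ny), nz = mean(nz))),
            by = c("ix", "iy", "iz")]
  data.table::setorder(agg, ix, iy, iz)
  N <- NULL
  if (has_n) {
    N <- as.matrix(agg[, c("nx", "ny", "nz")])
    len <- sqrt(rowSums(N^2))
    len[len < 1e-12] <- 1
    N <- N / len
  }
  point_cloud(as.matrix(agg[, c("x", "y", "z")]),
              labels = if (!is.null(cloud$labels)) cloud$labels[agg$first],
              branch_id = if (!is.null(cloud$branch_id)) cloud$branch_id[agg$first],
              normals = N)
}

#' Preprocess one scan
#'
#' Fixed order: ground-plane RANSAC, ground removal, statistical outlier
#' removal, voxel downsampling. Heights throughout the pipeline refer to the
#' plane fitted here.
#'
#' @param cloud raw [point_cloud()] including ground points.
#' @param config a [pipeline_config()] (or its `preprocess`-relevant subset).
#' @return A list with `cloud` (the cleaned, downsampled cloud), `plane`
#'   (the fitted [ground_plane()]) and removal counts.
#' @export
preprocess_cloud <- function(cloud, config = pipeline_config()) {
  plane <- fit_ground_plane(cloud, dist_thresh = config$ground$dist_thresh,
                            n_iter = config$ground$n_iter, seed = config$seed)
  ng <- remove_ground(cloud, plane, band = config$ground$band)
  if (n_points(ng) == 0)
    stop_treereg("no points remain above the ground plane", "treereg_degenerate_error")
  filt <- statistical_outlier_removal(ng, k = config$sor$k,
                                      std_mult = config$sor$std_mult)
  down <- voxel_downsample(filt, voxel = config$voxel$size)
  list(cloud = down, plane = plane,
       n_ground_removed = attr(ng, "n_removed"),
       n_outliers_removed = attr(filt, "n_removed"))
}
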