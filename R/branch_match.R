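# Branch-feature matching: extract key branch stubs in a radial ring around
# the trunk, describe each by (radius r, branch-trunk angle theta, centroid
# height h), gate all source x target pairings against per-feature
# tolerances, score survivors with a dynamically weighted fused residual,
# and pick the single best pair.

#' Matching configuration
#'
#' Tolerances and geometric windows of the branch-matching stage. Defaults
#' follow the published tuning: 5 mm radius, 15 degree angle and 50 mm
#' height tolerances; radial ring 0.07-0.14 m from the trunk axis; inlier
#' ratio gate 30%. The key height region, cluster gate and fitting controls
#' are engineering defaults, documented in the methods vignette.
#'
#' @param tol_r radius tolerance (m).
#' @param tol_theta angle tolerance (rad).
#' @param tol_h height tolerance (m).
#' @param ring_min,ring_max radial ring around the trunk axis (m).
#' @param min_inlier_ratio minimum cylinder inlier ratio for a candidate.
#' @param key_region `(h_lo, h_hi)` height window (m) for the key region.
#' @param cluster_tol Euclidean clustering tolerance (m).
#' @param cluster_size inclusive `(min, max)` cluster size gate (points).
#' @param cyl_dist_thresh branch cylinder inlier threshold (m).
#' @param cyl_n_iter RANSAC iterations per branch cluster.
#' @return An object of class `match_config`.
#' @export
match_config <- function(tol_r = 0.005, tol_theta = deg2rad(15), tol_h = 0.050,
                         ring_min = 0.07, ring_max = 0.14,
                         min_inlier_ratio = 0.30, key_region = c(0.2, 1.6),
                         cluster_tol = 0.012, cluster_size = c(40, 2000),
                         cyl_dist_thresh = 0.004, cyl_n_iter = 5000) {
  stopifnot(tol_r > 0, tol_theta > 0, tol_h > 0, ring_min < ring_max,
            key_region[1] < key_region[2])
  structure(list(tol_r = tol_r, tol_theta = tol_theta, tol_h = tol_h,
                 ring_min = ring_min, ring_max = ring_max,
                 min_inlier_ratio = min_inlier_ratio, key_region = key_region,
                 cluster_tol = cluster_tol, cluster_size = cluster_size,
                 cyl_dist_thresh = cyl_dist_thresh, cyl_n_iter = cyl_n_iter),
            class = "match_config")
}

#' Extract the key height region of a scan
#'
#' The tree's middle-lower section, where trunk and branches are thick,
#' wind-stable and visible from both stations.
#'
#' @param cloud a preprocessed [point_cloud()].
#' @param plane the scan's [ground_plane()].
#' @param cfg a [match_config()].
#' @return The [point_cloud()] restricted to heights in `cfg$key_region`.
#' @export
extract_key_region <- function(cloud, plane, cfg = match_config()) {
  h <- height_above_ground(cloud, plane)
  keep <- h >= cfg$key_region[1] & h <= cfg$key_region[2]
  if (!any(keep))
    stop_treereg("key height region contains no points; registration cannot proceed",
                 "treereg_empty_region")
  subset_cloud(cloud, keep)
}

#' Ring of branch stubs around the trunk
#'
#' Points whose perpendicular distance to the trunk axis lies in
#' `[ring_min, ring_max]` — past the geometrically variable branch-trunk
#' junction zone but close enough to stay cylindrical and wind-stable.
#'
#' @param key_cloud the key-region [point_cloud()].
#' @param trunk the trunk [cylinder3d()] fitted on the key region.
#' @param cfg a [match_config()].
#' @return The ring [point_cloud()] (possibly empty).
#' @export
segment_branch_ring <- function(key_cloud, trunk, cfg = match_config()) {
  d <- point_line_dist(key_cloud$points, trunk$axis_point, trunk$axis_dir)
  subset_cloud(key_cloud, d >= cfg$ring_min & d <= cfg$ring_max)
}

#' Branch features (r, theta, h)
#'
#' Radius of the fitted branch cylinder, angle between branch and trunk axes
#' folded into `[0, pi/2]` (orientation-free), and height of the segment's
#' point centroid above the ground.
#'
#' @param points the segment's member points (`n x 3`).
#' @param cylinder the branch [cylinder3d()].
#' @param trunk the trunk [cylinder3d()].
#' @param plane the scan's [ground_plane()].
#' @return A list with `r` (m), `theta` (rad) and `h` (m).
#' @export
branch_features <- function(points, cylinder, trunk, plane) {
  theta <- acos(clamp(abs(sum(cylinder$axis_dir * trunk$axis_dir)), 0, 1))
  h <- height_above_ground(colMeans(points), plane)
  list(r = cylinder$radius, theta = theta, h = h)
}

#' Branch segment candidates from the ring cloud
#'
#' Euclidean clustering with the size gate, per-cluster RANSAC cylinder fit
#' (unconstrained axis), inlier-ratio gate, and feature attachment. On
#' synthetic clouds the majority ground-truth branch id of each cluster is
#' carried along for evaluation.
#'
#' @param ring_cloud output of [segment_branch_ring()].
#' @param trunk the trunk [cylinder3d()] (for the angle feature).
#' @param plane the scan's [ground_plane()] (for the height feature).
#' @param cfg a [match_config()].
#' @param seed RNG seed fanned out per cluster.
#' @return A list of `branch_segment` objects (possibly empty), each with
#'   fields `cluster`, `cylinder`, `r`, `theta`, `h`, `inlier_count`,
#'   `gt_branch_id`.
#' @export
filter_candidates <- function(ring_cloud, trunk, plane, cfg = match_config(),
                              seed = 0) {
  clusters <- euclidean_cluster(ring_cloud, tolerance = cfg$cluster_tol,
                                min_size = cfg$cluster_size[1],
                                max_size = cfg$cluster_size[2])
  out <- list()
  for (i in seq_along(clusters)) {
    cl <- clusters[[i]]
    sub <- subset_cloud(ring_cloud, cl$indices)
    cyl <- tryCatch(
      # radius capped at 5 cm: primary apple branches never exceed a few cm,
      # and the cap stops near-planar clutter from passing as a giant cylinder
      ransac_cylinder(sub, dist_thresh = cfg$cyl_dist_thresh,
                      n_iter = cfg$cyl_n_iter, seed = seed + i,
                      radius_bounds = c(0.002, 0.05)),
      treereg_error = function(e) NULL)
    if (is.null(cyl) || cyl$inlier_ratio < cfg$min_inlier_ratio) next
    feats <- branch_features(sub$points, cyl, trunk, plane)
    gt <- NA_integer_
    if (!is.null(sub$branch_id)) {
      ids <- sub$branch_id[!is.na(sub$branch_id)]
      if (length(ids)) gt <- as.integer(names(which.max(table(ids))))
    }
    out[[length(out) + 1L]] <- structure(
      list(cluster = cl, cylinder = cyl, r = feats$r, theta = feats$theta,
           h = feats$h, inlier_count = length(cyl$inlier_idx),
           gt_branch_id = gt),
      class = "branch_segment")
  }
  out
}

#' @export
print.branch_segment <- function(x, ...) {
  cat(sprintf("<branch_segment: r = %.1f mm, theta = %.1f deg, h = %.3f m, %d inliers%s>\n",
              1000 * x$r, rad2deg(x$theta), x$h, x$inlier_count,
              if (!is.na(x$gt_branch_id)) paste0(", gt id ", x$gt_branch_id) else ""))
  invisible(x)
}

#' Per-feature threshold gate
#'
#' A candidate pairing survives only if all three residuals are strictly
#' below their tolerances.
#'
#' @param d_r,d_theta,d_h absolute residuals (m, rad, m).
#' @param cfg a [match_config()].
#' @return Logical.
#' @export
threshold_gate <- function(d_r, d_theta, d_h, cfg = match_config()) {
  d_r < cfg$tol_r && d_theta < cfg$tol_theta && d_h < cfg$tol_h
}

#' Dynamically weighted fused residual
#'
#' Each residual is normalized by its tolerance, `x_i = d_i / tol_i`; the
#' weight of feature `i` is `-ln(x_i)` renormalized to sum to one, so the
#' most consistent features dominate; the score is the weighted sum
#' `sum(w_i x_i)` (lower = more similar). Normalized residuals are clamped
#' to `[1e-6, 1 - 1e-6]` to keep the logarithms finite; when all three are
#' equal the analytic limit `w = 1/3` is used, making `score(x, x, x) = x`
#' exact.
#'
#' @param d_r,d_theta,d_h absolute residuals that already passed
#'   [threshold_gate()] (all `d_i / tol_i < 1`).
#' @param cfg a [match_config()].
#' @return A list with `score`, `w_r`, `w_theta`, `w_h` and the normalized
#'   residuals `x`.
#' @export
pair_score <- function(d_r, d_theta, d_h, cfg = match_config()) {
  x <- c(d_r / cfg$tol_r, d_theta / cfg$tol_theta, d_h / cfg$tol_h)
  if (any(x >= 1))
    stop_treereg("pair_score called on residuals beyond tolerance; run threshold_gate first",
                 "treereg_contract_error")
  eps <- 1e-6
  x <- clamp(x, eps, 1 - eps)
  if (max(x) - min(x) < 1e-15) {
    w <- rep(1 / 3, 3)
  } else {
    nl <- -log(x)
    w <- nl / sum(nl)
  }
  list(score = sum(w * x), w_r = w[1], w_theta = w[2], w_h = w[3], x = x)
}

#' Match branch segments between two scans
#'
#' Evaluates all source x target pairings: gate, score, then a greedy
#' one-to-one assignment in ascending score order (a pair is accepted only
#' if neither member is already taken). Among accepted pairs, the best is
#' the one with the highest combined cylinder inlier count (source +
#' target), ties broken by lower score — fit quality as the final
#' confidence measure.
#'
#' @param S,T lists of branch segments from [filter_candidates()].
#' @param cfg a [match_config()].
#' @return An object of class `match_result`: `best` (or `NULL`),
#'   `retained` (accepted pairs), `success`, and `table`, the full candidate
#'   score table as a data.frame (one row per gate-evaluated pairing).
#' @export
match_branches <- function(S, T, cfg = match_config()) {
  rows <- list()
  for (i in seq_along(S)) for (j in seq_along(T)) {
    d_r <- abs(S[[i]]$r - T[[j]]$r)
    d_theta <- abs(S[[i]]$theta - T[[j]]$theta)
    d_h <- abs(S[[i]]$h - T[[j]]$h)
    gate <- threshold_gate(d_r, d_theta, d_h, cfg)
    sc <- if (gate) pair_score(d_r, d_theta, d_h, cfg)
          else list(score = NA_real_, w_r = NA_real_, w_theta = NA_real_,
                    w_h = NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      src = i, tgt = j, d_r = d_r, d_theta = d_theta, d_h = d_h,
      w_r = sc$w_r, w_theta = sc$w_theta, w_h = sc$w_h,
      score = sc$score, gate = gate)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(src = integer(), tgt = integer(), d_r = numeric(),
                         d_theta = numeric(), d_h = numeric(), w_r = numeric(),
                         w_theta = numeric(), w_h = numeric(),
                         score = numeric(), gate = logical())
  pass <- tab[tab$gate, , drop = FALSE]
  pass <- pass[order(pass$score, pass$src, pass$tgt), , drop = FALSE]
  used_s <- logical(length(S)); used_t <- logical(length(T))
  accepted <- list()
  for (k in seq_len(nrow(pass))) {
    i <- pass$src[k]; j <- pass$tgt[k]
    if (used_s[i] || used_t[j]) next
    used_s[i] <- TRUE; used_t[j] <- TRUE
    accepted[[length(accepted) + 1L]] <- list(
      src = S[[i]], tgt = T[[j]], src_idx = i, tgt_idx = j,
      d_r = pass$d_r[k], d_theta = pass$d_theta[k], d_h = pass$d_h[k],
      w_r = pass$w_r[k], w_theta = pass$w_theta[k], w_h = pass$w_h[k],
      score = pass$score[k],
      inliers = S[[i]]$inlier_count + T[[j]]$inlier_count)
  }
  best <- NULL
  if (length(accepted)) {
    inl <- vapply(accepted, `[[`, 1, "inliers")
    scr <- vapply(accepted, `[[`, 1, "score")
    best <- accepted[[order(-inl, scr)[1]]]
  }
  structure(list(best = best, retained = accepted,
                 success = !is.null(best), table = tab),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$success)
    cat(sprintf("<match_result: success, best pair score %.4f (%d combined inliers), %d pair(s) retained>\n",
                x$best$score, x$best$inliers, length(x$retained)))
  else cat("<match_result: no admissible branch pairing (failure)>\n")
  invisible(x)
}

#' Dump the candidate score table
#' @param match a `match_result`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(match, path) {
  utils::write.csv(match$table, path, row.names = FALSE)
  invisible(path)
}
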