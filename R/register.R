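# Registration: closed-form coarse alignment (yaw about the intersection of
# the matched branch axes projected to XOY, translation from basal-trunk
# cylinder centers), then branch-only trimmed point-to-point ICP refinement.
# The full transform is T = Tf . T2 . T1.

#' ICP configuration
#'
#' @param overlap_ratio fraction of closest correspondences kept per
#'   iteration (trimming removes the rest).
#' @param max_iter iteration cap.
#' @param rel_rms_tol relative trimmed-RMS change for convergence.
#' @param max_corr_dist correspondences farther than this are dropped before
#'   trimming (m); default 5x the 8 mm voxel size.
#' @param branch_margin margin added to the trunk radius when carving the
#'   branch-only cloud (m).
#' @param drift_guard over-registration guard (m): if the fine stage would
#'   displace any branch point more than this from its coarse-aligned
#'   position, the refinement is rejected and the coarse pose kept. On
#'   opposed-station scans the two branch clouds are near-complementary
#'   half-shells whose only true overlap is the thin silhouette band;
#'   unguarded point-to-point ICP can lower its trimmed RMS by nesting the
#'   shells into each other, sliding about one branch radius along the
#'   station axis. Default 2x the voxel size. Raise it for scan pairs whose
#'   coarse alignment may be tens of millimeters off.
#' @return An object of class `icp_config`.
#' @export
icp_config <- function(overlap_ratio = 0.90, max_iter = 50, rel_rms_tol = 1e-5,
                       max_corr_dist = 0.040, branch_margin = 0.015,
                       drift_guard = 0.016) {
  stopifnot(overlap_ratio > 0, overlap_ratio <= 1, max_iter >= 1,
            drift_guard > 0)
  structure(list(overlap_ratio = overlap_ratio, max_iter = max_iter,
                 rel_rms_tol = rel_rms_tol, max_corr_dist = max_corr_dist,
                 branch_margin = branch_margin, drift_guard = drift_guard),
            class = "icp_config")
}

# Flip a branch axis so it points away from the trunk axis.
.orient_away_from_trunk <- function(cyl, trunk) {
  w <- cyl$axis_point - trunk$axis_point
  foot <- trunk$axis_point + sum(w * trunk$axis_dir) * trunk$axis_dir
  v <- cyl$axis_point - foot
  if (sqrt(sum(v^2)) > 1e-9 && sum(cyl$axis_dir * v) < 0) cyl$axis_dir <- -cyl$axis_dir
  cyl
}

# XOY point where the trunk axis crosses z = 0 (fallback rotation center).
.trunk_footprint_xoy <- function(trunk) {
  d <- trunk$axis_dir
  if (abs(d[3]) < 1e-9) return(trunk$axis_point[1:2])
  t <- -trunk$axis_point[3] / d[3]
  (trunk$axis_point + t * d)[1:2]
}

#' Coarse rotation from the matched branch pair
#'
#' Both branch axes are oriented to point away from their trunk axis,
#' projected onto the XOY plane, and intersected; the intersection `O` is
#' the rotation center and the signed angle between the projected
#' directions the yaw `alpha`. `T1` rotates by `alpha` about the vertical
#' line through `O`. If the projections are near-parallel (yaw close to 0
#' or pi) the rotation center falls back to the source trunk-axis XOY
#' footprint with `alpha` the signed angle between the direction vectors.
#'
#' @param src_cyl,tgt_cyl matched branch [cylinder3d()]s.
#' @param src_trunk the source trunk [cylinder3d()].
#' @param tgt_trunk the target trunk [cylinder3d()] (defaults to
#'   `src_trunk`, for pre-oriented inputs).
#' @return A list with `O` (length 2), `alpha` (rad) and `T1`
#'   ([rigid_transform()]).
#' @export
rotation_from_branches <- function(src_cyl, tgt_cyl, src_trunk,
                                   tgt_trunk = src_trunk) {
  src_cyl <- .orient_away_from_trunk(src_cyl, src_trunk)
  tgt_cyl <- .orient_away_from_trunk(tgt_cyl, tgt_trunk)
  src_line <- tryCatch(project_axis_xoy(src_cyl), treereg_degenerate_error = function(e)
    stop_treereg("matched source branch axis is vertical; no yaw can be derived",
                 "treereg_coarse_failure"))
  tgt_line <- tryCatch(project_axis_xoy(tgt_cyl), treereg_degenerate_error = function(e)
    stop_treereg("matched target branch axis is vertical; no yaw can be derived",
                 "treereg_coarse_failure"))
  res <- tryCatch(line_intersection_2d(src_line, tgt_line),
                  treereg_parallel_lines = function(e) NULL)
  if (is.null(res)) {
    O <- .trunk_footprint_xoy(src_trunk)
    cr <- src_line$dir[1] * tgt_line$dir[2] - src_line$dir[2] * tgt_line$dir[1]
    dt <- sum(src_line$dir * tgt_line$dir)
    alpha <- atan2(cr, dt)
    res <- list(O = O, alpha = alpha)
  }
  list(O = res$O, alpha = res$alpha, T1 = rt_rot_z_about(res$alpha, res$O))
}

#' Coarse translation from basal trunk centers
#'
#' From each scan the trunk slab at heights 0.20-0.30 m above its ground
#' plane is extracted (below the first branches, above root-collar
#' irregularities), a vertical-prior RANSAC cylinder is fitted, and the
#' geometric center `G` is read off the fitted axis at 0.25 m height. `T2`
#' translates `G_src` (after `after_T1`) onto `G_tgt`.
#'
#' @param src_cloud,tgt_cloud preprocessed, ground-free scans in their own
#'   frames.
#' @param src_plane,tgt_plane the scans' [ground_plane()]s.
#' @param after_T1 the yaw [rigid_transform()] already applied to the source.
#' @param seed RNG seed for the two cylinder fits.
#' @param band trunk slab height interval (m).
#' @param dist_thresh trunk cylinder inlier threshold (m).
#' @param n_iter RANSAC iterations.
#' @return A list with `G_src`, `G_tgt` (3-vectors) and `T2`
#'   ([rigid_transform()]).
#' @export
translation_from_trunks <- function(src_cloud, tgt_cloud, src_plane, tgt_plane,
                                    after_T1 = rt_identity(), seed = 0,
                                    band = c(0.20, 0.30), dist_thresh = 0.005,
                                    n_iter = 5000) {
  src_rot <- apply_transform(src_cloud, after_T1)
  src_plane_rot <- transform_plane(src_plane, after_T1)
  center_at <- function(cloud, plane, sd) {
    h <- height_above_ground(cloud, plane)
    slab <- subset_cloud(cloud, h >= band[1] & h <= band[2])
    if (n_points(slab) < 6)
      stop_treereg("trunk slab for translation is (nearly) empty",
                   "treereg_coarse_failure")
    cyl <- tryCatch(
      ransac_cylinder(slab, dist_thresh = dist_thresh, n_iter = n_iter,
                      seed = sd, axis_prior = c(0, 0, 1),
                      max_axis_dev = deg2rad(10)),
      treereg_error = function(e)
        stop_treereg(paste0("basal trunk cylinder fit failed: ", conditionMessage(e)),
                     "treereg_coarse_failure"))
    # point on the fitted axis at mid-band height above this scan's ground
    h0 <- height_above_ground(cyl$axis_point, plane)
    dh <- sum(cyl$axis_dir * plane$normal)
    cyl$axis_point + (mean(band) - h0) / dh * cyl$axis_dir
  }
  G_src <- center_at(src_rot, src_plane_rot, seed)
  G_tgt <- center_at(tgt_cloud, tgt_plane, seed + 1)
  list(G_src = G_src, G_tgt = G_tgt, T2 = rt_translation(G_tgt - G_src))
}

#' Coarse registration
#'
#' Runs [rotation_from_branches()] on the best matched pair, then
#' [translation_from_trunks()], and composes `Tc = T2 . T1`.
#'
#' @param src_cloud,tgt_cloud preprocessed scans.
#' @param match a successful `match_result`.
#' @param src_trunk,tgt_trunk per-scan trunk [cylinder3d()]s.
#' @param src_plane,tgt_plane per-scan [ground_plane()]s.
#' @param seed RNG seed.
#' @return An object of class `coarse_alignment` with `O`, `alpha`, `T1`,
#'   `G_src`, `G_tgt`, `T2` and `Tc`.
#' @export
coarse_register <- function(src_cloud, tgt_cloud, match, src_trunk, tgt_trunk,
                            src_plane, tgt_plane, seed = 0) {
  if (!isTRUE(match$success))
    stop_treereg("coarse registration requires a successful branch match",
                 "treereg_match_failure")
  rot <- rotation_from_branches(match$best$src$cylinder, match$best$tgt$cylinder,
                                src_trunk, tgt_trunk)
  tra <- translation_from_trunks(src_cloud, tgt_cloud, src_plane, tgt_plane,
                                 after_T1 = rot$T1, seed = seed)
  Tc <- rigid_transform(unclass(tra$T2) %*% unclass(rot$T1))
  structure(list(O = rot$O, alpha = rot$alpha, T1 = rot$T1,
                 G_src = tra$G_src, G_tgt = tra$G_tgt, T2 = tra$T2, Tc = Tc),
            class = "coarse_alignment")
}

#' @export
print.coarse_alignment <- function(x, ...) {
  cat(sprintf("<coarse_alignment: alpha = %.2f deg about O = (%.3f, %.3f), |t2| = %.3f m>\n",
              rad2deg(x$alpha), x$O[1], x$O[2],
              sqrt(sum((x$G_tgt - x$G_src)^2))))
  invisible(x)
}

#' Branch-only cloud for fine registration
#'
#' Removes the trunk (points within `trunk radius + margin` of the trunk
#' axis); ground is assumed already removed. The geometrically simple,
#' highly overlapping trunk would otherwise dominate the ICP error metric
#' and drive over-registration.
#'
#' @param cloud a ground-free [point_cloud()].
#' @param trunk the scan's trunk [cylinder3d()].
#' @param plane the scan's [ground_plane()] (kept for interface symmetry).
#' @param margin radial margin beyond the fitted trunk radius (m).
#' @return The branch-only [point_cloud()].
#' @export
extract_branch_only <- function(cloud, trunk, plane = NULL, margin = 0.015) {
  d <- point_line_dist(cloud$points, trunk$axis_point, trunk$axis_dir)
  out <- subset_cloud(cloud, d >= trunk$radius + margin)
  if (n_points(out) == 0)
    stop_treereg("no branch points remain for fine registration",
                 "treereg_fine_failure")
  out
}

# Closed-form least-squares rigid transform mapping A onto B (Kabsch /
# SVD of the cross-covariance, reflection-corrected).
.rigid_solve <- function(A, B) {
  mu_a <- colMeans(A); mu_b <- colMeans(B)
  H <- crossprod(sweep(A, 2, mu_a), sweep(B, 2, mu_b))
  sv <- svd(H)
  S <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% S %*% t(sv$u)
  t <- mu_b - as.vector(R %*% mu_a)
  m <- diag(4); m[1:3, 1:3] <- R; m[1:3, 4] <- t
  rigid_transform(m, tol = 1e-6)
}

#' Trimmed point-to-point ICP
#'
#' Iterates exact nearest-neighbor correspondences, drops pairs farther
#' than `max_corr_dist`, keeps the closest `ceil(overlap_ratio * N)` of the
#' remainder, and solves the least-squares rigid transform on the kept
#' pairs. Stops when the relative trimmed-RMS change falls below
#' `rel_rms_tol` or after `max_iter` iterations; a step that would increase
#' the trimmed RMS is rolled back, so the reported RMS sequence is
#' non-increasing.
#'
#' @param src,tgt non-empty [point_cloud()]s; `src` should already be
#'   coarse-aligned.
#' @param cfg an [icp_config()].
#' @return A list with `transform` (`Tf`), `final_rms` (m), `n_iter` and
#'   `rms_history`.
#' @export
trimmed_icp <- function(src, tgt, cfg = icp_config()) {
  if (n_points(src) == 0 || n_points(tgt) == 0)
    stop_treereg("ICP requires non-empty clouds", "treereg_fine_failure")
  P0 <- src$points
  Q <- tgt$points
  T_acc <- diag(4)
  rms_hist <- numeric(0)
  prev_rms <- Inf
  n_used <- 0L
  for (it in seq_len(cfg$max_iter)) {
    P <- transform_points(P0, rigid_transform(T_acc))
    nn <- cpp_nn(P, Q)
    ok <- which(nn$dist <= cfg$max_corr_dist)
    if (length(ok) < 3)
      stop_treereg("fewer than 3 ICP correspondences within range",
                   "treereg_fine_failure")
    keep_n <- ceiling(cfg$overlap_ratio * length(ok))
    kept <- ok[order(nn$dist[ok])[seq_len(keep_n)]]
    if (length(kept) < 3)
      stop_treereg("fewer than 3 ICP correspondences after trimming",
                   "treereg_fine_failure")
    rms <- sqrt(mean(nn$dist[kept]^2))
    if (rms > prev_rms + 1e-15) break  # roll back: keep the previous pose
    rms_hist <- c(rms_hist, rms)
    n_used <- it
    converged <- is.finite(prev_rms) &&
      abs(prev_rms - rms) < cfg$rel_rms_tol * max(prev_rms, 1e-300)
    prev_rms <- rms
    if (converged) break
    dT <- .rigid_solve(P[kept, , drop = FALSE], Q[nn$idx[kept], , drop = FALSE])
    T_acc <- unclass(dT) %*% T_acc
  }
  list(transform = rigid_transform(T_acc), final_rms = prev_rms,
       n_iter = n_used, rms_history = rms_hist)
}

#' Fine registration
#'
#' Extracts the branch-only clouds of both scans, applies the coarse
#' transform to the source, runs [trimmed_icp()], and returns the composed
#' transform `T = Tf . Tc` together with the ICP diagnostics. An
#' over-registration guard protects the pose: on opposed-station scans the
#' two branch clouds are near-complementary half-shells whose only true
#' overlap is the thin silhouette band, and an unconstrained refinement can
#' lower its own trimmed RMS by nesting the shells — a drift of about one
#' branch radius along the station axis. The rim lines still constrain the
#' rotation tightly, so when the refinement displaces any branch point more
#' than `cfg$drift_guard` from its coarse-aligned position
#' (`over_registration = TRUE`), the ICP rotation is kept but the
#' translation is re-anchored on the basal trunk centers (the same
#' construction the coarse stage uses); if that re-anchoring fails the
#' coarse pose is returned unchanged.
#'
#' @param src_cloud,tgt_cloud preprocessed scans in their own frames.
#' @param coarse a [coarse_register()] result.
#' @param src_trunk,tgt_trunk per-scan trunk [cylinder3d()]s.
#' @param src_plane,tgt_plane per-scan [ground_plane()]s.
#' @param cfg an [icp_config()].
#' @param seed RNG seed for the recovery trunk fits.
#' @return A list with `transform` (the full `T`), `Tf`, `icp`,
#'   `over_registration` and `drift` (m).
#' @export
fine_register <- function(src_cloud, tgt_cloud, coarse, src_trunk, tgt_trunk,
                          src_plane, tgt_plane, cfg = icp_config(), seed = 0) {
  src_b <- extract_branch_only(src_cloud, src_trunk, src_plane,
                               margin = cfg$branch_margin)
  tgt_b <- extract_branch_only(tgt_cloud, tgt_trunk, tgt_plane,
                               margin = cfg$branch_margin)
  src_bc <- apply_transform(src_b, coarse$Tc)
  icp <- trimmed_icp(src_bc, tgt_b, cfg)
  drift <- max(sqrt(rowSums((transform_points(src_bc$points, icp$transform) -
                               src_bc$points)^2)))
  over <- drift > cfg$drift_guard
  if (!over) {
    T_full <- rigid_transform(unclass(icp$transform) %*% unclass(coarse$Tc))
    Tf <- icp$transform
  } else {
    T_icp <- rigid_transform(unclass(icp$transform) %*% unclass(coarse$Tc))
    T_full <- tryCatch({
      tra <- translation_from_trunks(src_cloud, tgt_cloud, src_plane, tgt_plane,
                                     after_T1 = T_icp, seed = seed)
      cand <- rigid_transform(unclass(tra$T2) %*% unclass(T_icp))
      # the recovered pose must itself stay within the guard of the coarse
      # pose, so the fine stage is bounded-drift by construction
      dTc <- unclass(cand) %*% unclass(rt_inverse(coarse$Tc))
      disp <- max(sqrt(rowSums((transform_points(src_bc$points,
                                                 rigid_transform(dTc)) -
                                  src_bc$points)^2)))
      if (disp <= cfg$drift_guard) cand else coarse$Tc
    }, treereg_error = function(e) coarse$Tc)
    Tf <- rigid_transform(unclass(T_full) %*% unclass(rt_inverse(coarse$Tc)))
  }
  list(transform = T_full, Tf = Tf, icp = icp, over_registration = over,
       drift = drift)
}
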