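# Evaluation metrics: axis-angle rotation error, translation error,
# pointwise error (with per-axis components), branch-match success against
# ground-truth correspondence, model completeness and structural parameters.
# Internal units are radians and meters; reporting helpers convert to
# mrad / mm / cm.

.check_rotation <- function(R, tol = 1e-6) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3)) || max(abs(crossprod(R) - diag(3))) > tol ||
      det(R) < 0)
    stop_treereg("input is not a proper rotation matrix", "treereg_contract_error")
  R
}

#' Rotation angle of a rotation matrix
#'
#' Axis-angle magnitude `beta = arccos((tr(R) - 1) / 2)`, with the trace
#' argument clamped to `[-1, 1]` against floating-point overshoot.
#'
#' @param R a 3x3 rotation matrix.
#' @return Angle in radians, in `[0, pi]`.
#' @export
rotation_angle <- function(R) {
  R <- .check_rotation(R)
  acos(clamp((sum(diag(R)) - 1) / 2, -1, 1))
}

#' Rotation error between two rotations
#'
#' `e_R = arccos((tr(R_gt R^T) - 1) / 2)`: the angle of the residual
#' rotation, symmetric in its arguments.
#'
#' @param R,R_gt 3x3 rotation matrices.
#' @param unit `"rad"` (default) or `"mrad"`.
#' @return Rotation error in the requested unit.
#' @export
rotation_error <- function(R, R_gt, unit = c("rad", "mrad")) {
  unit <- match.arg(unit)
  e <- rotation_angle(.check_rotation(R_gt) %*% t(.check_rotation(R)))
  if (unit == "mrad") 1000 * e else e
}

#' Translation error
#'
#' Euclidean distance between the estimated and ground-truth translation
#' vectors.
#'
#' @param t,t_gt length-3 translation vectors (m).
#' @param unit `"m"` (default) or `"mm"`.
#' @return Translation error in the requested unit.
#' @export
translation_error <- function(t, t_gt, unit = c("m", "mm")) {
  unit <- match.arg(unit)
  e <- sqrt(sum((as.numeric(t) - as.numeric(t_gt))^2))
  if (unit == "mm") 1000 * e else e
}

#' Pointwise registration error
#'
#' Mean Euclidean distance between source points mapped by the estimated
#' and by the ground-truth transform, plus per-axis means of the absolute
#' coordinate differences.
#'
#' @param src the source [point_cloud()] (non-empty).
#' @param T,T_gt estimated and ground-truth [rigid_transform()]s.
#' @param unit `"m"` (default) or `"mm"`.
#' @return A list with `e_p` and `e_p_xyz` (length 3).
#' @export
pointwise_error <- function(src, T, T_gt, unit = c("m", "mm")) {
  unit <- match.arg(unit)
  if (n_points(src) == 0)
    stop_treereg("pointwise error needs a non-empty source cloud",
                 "treereg_contract_error")
  D <- transform_points(src$points, T) - transform_points(src$points, T_gt)
  e_p <- mean(sqrt(rowSums(D^2)))
  e_xyz <- colMeans(abs(D))
  s <- if (unit == "mm") 1000 else 1
  list(e_p = s * e_p, e_p_xyz = s * e_xyz)
}

#' Branch-match success against ground truth
#'
#' A trial succeeds when matching produced a best pair and that pair's
#' (source, target) branch identities form a ground-truth correspondence.
#'
#' @param match a `match_result`.
#' @param correspondence a two-column matrix/data.frame of corresponding
#'   (source id, target id) pairs, or `NULL` for the identity map
#'   (synthetic scans share branch ids).
#' @return Logical.
#' @export
match_success <- function(match, correspondence = NULL) {
  if (!isTRUE(match$success)) return(FALSE)
  s <- match$best$src$gt_branch_id
  t <- match$best$tgt$gt_branch_id
  if (is.na(s) || is.na(t))
    stop_treereg("ground-truth branch ids are missing from the matched segments",
                 "treereg_eval_error")
  if (is.null(correspondence)) return(s == t)
  cm <- as.matrix(correspondence)
  any(cm[, 1] == s & cm[, 2] == t)
}

#' Model completeness
#'
#' Directional coverage: the fraction of reference points whose nearest
#' neighbor in the test cloud lies within `thresh`.
#'
#' @param test the reconstructed [point_cloud()].
#' @param reference the ground-truth [point_cloud()] (non-empty).
#' @param thresh coverage distance (m), default 5 mm.
#' @return Fraction in `[0, 1]`.
#' @export
completeness <- function(test, reference, thresh = 0.005) {
  if (n_points(reference) == 0)
    stop_treereg("completeness needs a non-empty reference cloud",
                 "treereg_contract_error")
  if (n_points(test) == 0) return(0)
  nn <- cpp_nn(reference$points, test$points)
  mean(nn$dist <= thresh)
}

#' Structural parameters of a registered tree model
#'
#' Tree height is the maximum height above the fitted ground plane; the
#' basal trunk diameter comes from a vertical-prior cylinder fitted on the
#' 0.20-0.30 m trunk slab; primary branches are counted from per-branch
#' cylinders fitted in the 0.07-0.14 m radial ring around the trunk axis
#' (the same clustering/fitting machinery as matching), keeping those with
#' basal diameter above 1 cm.
#'
#' @param cloud a registered, ground-free [point_cloud()] referenced to
#'   `plane`.
#' @param plane the [ground_plane()].
#' @param seed RNG seed for the cylinder fits.
#' @param cfg a [match_config()] supplying ring and fitting controls.
#' @return An object of class `structural_params` with `tree_height_cm`,
#'   `basal_trunk_diameter_cm`, `n_primary_branches`,
#'   `max_branch_diameter_cm`, `avg_branch_diameter_cm`.
#' @export
structural_params <- function(cloud, plane, seed = 0, cfg = match_config()) {
  h <- height_above_ground(cloud, plane)
  tree_height <- max(h)
  slab <- subset_cloud(cloud, h >= 0.20 & h <= 0.30)
  if (n_points(slab) < 6)
    stop_treereg("trunk slab is empty; cannot measure the basal diameter",
                 "treereg_eval_error")
  basal <- tryCatch(
    ransac_cylinder(slab, dist_thresh = 0.005, n_iter = 5000, seed = seed,
                    axis_prior = c(0, 0, 1), max_axis_dev = deg2rad(10)),
    treereg_error = function(e)
      stop_treereg(paste0("basal trunk fit failed: ", conditionMessage(e)),
                   "treereg_eval_error"))
  # taller trunk fit for a stable ring axis over the whole crown
  key <- subset_cloud(cloud, h >= cfg$key_region[1] & h <= cfg$key_region[2])
  trunk <- tryCatch(
    ransac_cylinder(key, dist_thresh = 0.005, n_iter = 5000, seed = seed + 1,
                    axis_prior = c(0, 0, 1), max_axis_dev = deg2rad(10)),
    treereg_error = function(e) basal)
  d <- point_line_dist(cloud$points, trunk$axis_point, trunk$axis_dir)
  ring <- subset_cloud(cloud, d >= cfg$ring_min & d <= cfg$ring_max)
  segs <- filter_candidates(ring, trunk, plane, cfg = cfg, seed = seed + 2)
  diam <- 2 * vapply(segs, `[[`, 1, "r")
  diam <- diam[diam > 0.01]
  structure(list(tree_height_cm = 100 * tree_height,
                 basal_trunk_diameter_cm = 200 * basal$radius,
                 n_primary_branches = length(diam),
                 max_branch_diameter_cm = if (length(diam)) 100 * max(diam) else NA_real_,
                 avg_branch_diameter_cm = if (length(diam)) 100 * mean(diam) else NA_real_),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf(paste0("<structural_params: height %.1f cm, basal diameter %.2f cm, ",
                     "%d primary branches (max %.2f / avg %.2f cm)>\n"),
              x$tree_height_cm, x$basal_trunk_diameter_cm, x$n_primary_branches,
              x$max_branch_diameter_cm, x$avg_branch_diameter_cm))
  invisible(x)
}

#' Registration report
#'
#' Bundles the evaluation of an estimated transform against ground truth in
#' reporting units (mrad / mm), optionally with match success and
#' completeness.
#'
#' @param T,T_gt estimated and ground-truth [rigid_transform()]s.
#' @param src the source [point_cloud()] used for the pointwise error.
#' @param match optional `match_result` for the success flag.
#' @param correspondence optional ground-truth correspondence for
#'   [match_success()].
#' @param completeness optional completeness fraction to carry through.
#' @return An object of class `registration_report` with `e_R_mrad`,
#'   `e_t_mm`, `e_p_mm`, `e_p_xyz_mm`, `success`, `completeness`.
#' @export
registration_report <- function(T, T_gt, src, match = NULL,
                                correspondence = NULL, completeness = NULL) {
  pw <- pointwise_error(src, T, T_gt, unit = "mm")
  structure(list(
    e_R_mrad = rotation_error(rotation_block(T), rotation_block(T_gt), unit = "mrad"),
    e_t_mm = translation_error(translation_vec(T), translation_vec(T_gt), unit = "mm"),
    e_p_mm = pw$e_p, e_p_xyz_mm = pw$e_p_xyz,
    success = if (!is.null(match)) match_success(match, correspondence) else NA,
    completeness = completeness), class = "registration_report")
}

#' @export
print.registration_report <- function(x, ...) {
  cat(sprintf("<registration_report: e_R %.2f mrad, e_t %.2f mm, e_p %.2f mm (x %.2f, y %.2f, z %.2f)%s%s>\n",
              x$e_R_mrad, x$e_t_mm, x$e_p_mm, x$e_p_xyz_mm[1], x$e_p_xyz_mm[2],
              x$e_p_xyz_mm[3],
              if (!is.na(x$success)) paste0(", success ", x$success) else "",
              if (!is.null(x$completeness))
                sprintf(", completeness %.1f%%", 100 * x$completeness) else ""))
  invisible(x)
}
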