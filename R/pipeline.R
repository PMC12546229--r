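# End-to-end pipeline driver: preprocess -> branch match -> coarse ->
# fine, with one configuration object holding every stage default and one
# top-level seed fanned out deterministically per stage.

#' Pipeline configuration
#'
#' Nested defaults for every stage. Published constants sit here exactly
#' once: SOR k = 5 / multiplier 0.1, voxel 8 mm, radial ring 0.07-0.14 m,
#' inlier-ratio gate 30%, feature tolerances 5 mm / 15 deg / 50 mm, trunk
#' slab 0.20-0.30 m, ICP overlap ratio 90%, completeness threshold 5 mm.
#'
#' @param ... named overrides, e.g. `pipeline_config(voxel = list(size = 0.01))`.
#'   Nested lists are merged field-by-field.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ground = list(dist_thresh = 0.010, band = 0.020, n_iter = 1000),
    sor = list(k = 5, std_mult = 0.1),
    voxel = list(size = 0.008),
    cylinder = list(trunk_dist_thresh = 0.005, branch_dist_thresh = 0.004,
                    n_iter = 5000, trunk_max_axis_dev = deg2rad(10)),
    cluster = list(tol = 0.012, min_size = 40, max_size = 2000),
    match = list(tol_r = 0.005, tol_theta = deg2rad(15), tol_h = 0.050,
                 ring_min = 0.07, ring_max = 0.14, min_inlier_ratio = 0.30,
                 key_region = c(0.2, 1.6)),
    icp = list(overlap_ratio = 0.90, max_iter = 50, rel_rms_tol = 1e-5,
               max_corr_dist = 0.040, branch_margin = 0.015,
               drift_guard = 0.016),
    trunk_band = c(0.20, 0.30),
    metrics = list(completeness_thresh = 0.005),
    seed = 0
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

# The match_config view of a pipeline_config.
.as_match_config <- function(cfg) {
  match_config(tol_r = cfg$match$tol_r, tol_theta = cfg$match$tol_theta,
               tol_h = cfg$match$tol_h, ring_min = cfg$match$ring_min,
               ring_max = cfg$match$ring_max,
               min_inlier_ratio = cfg$match$min_inlier_ratio,
               key_region = cfg$match$key_region,
               cluster_tol = cfg$cluster$tol,
               cluster_size = c(cfg$cluster$min_size, cfg$cluster$max_size),
               cyl_dist_thresh = cfg$cylinder$branch_dist_thresh,
               cyl_n_iter = cfg$cylinder$n_iter)
}

.as_icp_config <- function(cfg) {
  icp_config(overlap_ratio = cfg$icp$overlap_ratio, max_iter = cfg$icp$max_iter,
             rel_rms_tol = cfg$icp$rel_rms_tol,
             max_corr_dist = cfg$icp$max_corr_dist,
             branch_margin = cfg$icp$branch_margin,
             drift_guard = cfg$icp$drift_guard)
}

#' Register two opposed scans of one tree
#'
#' Full pipeline on two raw scans (ground included, meters, z vertical):
#' preprocessing, key-region trunk fits, branch-ring candidate extraction,
#' dynamically weighted branch matching, closed-form coarse alignment and
#' branch-only trimmed ICP. Classed errors signal the failure stage
#' (`treereg_match_failure`, `treereg_coarse_failure`,
#' `treereg_fine_failure`), mirroring the real-world case where no branch
#' pairing passes the feature gates.
#'
#' @param source,target raw [point_cloud()]s in their own scanner frames.
#' @param config a [pipeline_config()].
#' @return An object of class `treereg_result`: `transform` (the full `T`
#'   mapping source to target), `coarse`, `fine`, `match`, per-scan
#'   `planes`, `trunks`, preprocessed `clouds` and candidate segment lists.
#' @examples
#' \donttest{
#' tree <- generate_tree(tree_spec(surface_sampling = 0.005, seed = 7))
#' pair <- simulate_two_stations(tree, seed = 7)
#' res <- register_scans(pair$source, pair$target)
#' registration_report(res$transform, pair$T_gt, res$clouds$source)
#' }
#' @export
register_scans <- function(source, target, config = pipeline_config()) {
  mcfg <- .as_match_config(config)
  seed <- config$seed

  pre_s <- preprocess_cloud(source, config)
  pre_t <- preprocess_cloud(target, config)

  fit_trunk <- function(pre, sd) {
    key <- extract_key_region(pre$cloud, pre$plane, mcfg)
    trunk <- tryCatch(
      ransac_cylinder(key, dist_thresh = config$cylinder$trunk_dist_thresh,
                      n_iter = config$cylinder$n_iter, seed = sd,
                      axis_prior = c(0, 0, 1),
                      max_axis_dev = config$cylinder$trunk_max_axis_dev),
      treereg_error = function(e)
        stop_treereg(paste0("trunk fit failed: ", conditionMessage(e)),
                     "treereg_match_failure"))
    list(key = key, trunk = trunk)
  }
  ks <- fit_trunk(pre_s, seed + 11L)
  kt <- fit_trunk(pre_t, seed + 12L)

  ring_s <- segment_branch_ring(ks$key, ks$trunk, mcfg)
  ring_t <- segment_branch_ring(kt$key, kt$trunk, mcfg)
  S <- filter_candidates(ring_s, ks$trunk, pre_s$plane, mcfg, seed = seed + 100L)
  T_ <- filter_candidates(ring_t, kt$trunk, pre_t$plane, mcfg, seed = seed + 200L)

  match <- match_branches(S, T_, mcfg)
  if (!match$success)
    stop_treereg("no branch pairing passed the feature gates; registration failed",
                 "treereg_match_failure")

  coarse <- coarse_register(pre_s$cloud, pre_t$cloud, match, ks$trunk, kt$trunk,
                            pre_s$plane, pre_t$plane, seed = seed + 300L)
  fine <- fine_register(pre_s$cloud, pre_t$cloud, coarse, ks$trunk, kt$trunk,
                        pre_s$plane, pre_t$plane, .as_icp_config(config),
                        seed = seed + 400L)

  structure(list(transform = fine$transform, coarse = coarse, fine = fine,
                 match = match,
                 planes = list(source = pre_s$plane, target = pre_t$plane),
                 trunks = list(source = ks$trunk, target = kt$trunk),
                 clouds = list(source = pre_s$cloud, target = pre_t$cloud),
                 candidates = list(source = S, target = T_),
                 config = config),
            class = "treereg_result")
}

#' @export
print.treereg_result <- function(x, ...) {
  cat("<treereg_result>\n  coarse: ")
  print(x$coarse)
  cat(sprintf("  fine ICP: %d iteration(s), trimmed RMS %.2f mm\n",
              x$fine$icp$n_iter, 1000 * x$fine$icp$final_rms))
  cat("  transform:\n")
  print(unclass(round(unclass(x$transform), 6)))
  invisible(x)
}

#' Evaluate a pipeline result against ground truth
#'
#' @param result a `treereg_result` (or a bare [rigid_transform()]).
#' @param T_gt ground-truth [rigid_transform()].
#' @param source source cloud for the pointwise error (defaults to the
#'   preprocessed source stored in `result`).
#' @param correspondence optional ground-truth branch correspondence.
#' @return A [registration_report()].
#' @export
evaluate_registration <- function(result, T_gt, source = NULL,
                                  correspondence = NULL) {
  if (inherits(result, "treereg_result")) {
    if (is.null(source)) source <- result$clouds$source
    registration_report(result$transform, T_gt, source, match = result$match,
                        correspondence = correspondence)
  } else {
    registration_report(result, T_gt, source)
  }
}

#' Persist a pipeline result
#'
#' Writes the transform JSON (matrix plus coarse diagnostics and ICP
#' stats), the plain-text 4x4 matrix, the candidate score table CSV, and
#' optionally the registered merged cloud as binary PLY.
#'
#' @param result a `treereg_result`.
#' @param dir output directory (created if needed).
#' @param merged_cloud write `registered.ply` (transformed source + target)?
#' @return `dir`, invisibly.
#' @export
save_result <- function(result, dir, merged_cloud = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_transform_json(result$transform, file.path(dir, "transform.json"),
    extra = list(alpha_rad = result$coarse$alpha, O = result$coarse$O,
                 G_src = result$coarse$G_src, G_tgt = result$coarse$G_tgt,
                 icp = list(iters = result$fine$icp$n_iter,
                            final_rms = result$fine$icp$final_rms)))
  write_transform_matrix(result$transform, file.path(dir, "transform.txt"))
  write_score_table(result$match, file.path(dir, "score_table.csv"))
  if (merged_cloud) {
    src <- apply_transform(result$clouds$source, result$transform)
    merged <- point_cloud(rbind(src$points, result$clouds$target$points))
    write_cloud(merged, file.path(dir, "registered.ply"), binary = TRUE)
  }
  invisible(dir)
}
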