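# A tiny deterministic "tree": vertical trunk plus four clean branch stubs
# at distinct heights/angles/radii, used to exercise the ring and candidate
# machinery without the full simulator.
stub_scene <- function(radii = c(0.008, 0.010, 0.012, 0.016),
                       heights = c(0.5, 0.8, 1.1, 1.4),
                       azimuths = c(0, pi / 2, pi, 3 * pi / 2),
                       angles = c(90, 80, 70, 60) * pi / 180,
                       sigma = 0, seed = 1) {
  trunk <- cyl_points(radius = 0.03, len = 1.8, spacing = 0.006,
                      sigma = sigma, seed = seed)
  pts <- list(trunk)
  labs <- list(rep("trunk", nrow(trunk)))
  ids <- list(rep(NA_integer_, nrow(trunk)))
  for (i in seq_along(radii)) {
    u <- c(cos(azimuths[i]), sin(azimuths[i]), 0)
    dir <- cos(angles[i]) * c(0, 0, 1) + sin(angles[i]) * u
    st <- c(0, 0, heights[i]) + 0.025 * u
    B <- cyl_points(radius = radii[i], len = 0.2, base = st, dir = dir,
                    spacing = 0.004, sigma = sigma, seed = seed + i)
    pts[[i + 1]] <- B
    labs[[i + 1]] <- rep("branch", nrow(B))
    ids[[i + 1]] <- rep(i, nrow(B))
  }
  point_cloud(do.call(rbind, pts), labels = unlist(labs),
              branch_id = unlist(ids))
}

scene_trunk <- cylinder3d(c(0, 0, 0), c(0, 0, 1), 0.03)
scene_plane <- ground_plane(c(0, 0, 1), 0)

test_that("key-region extraction is a pure height window", {
  sc <- stub_scene()
  cfg <- match_config(key_region = c(0.2, 1.6))
  key <- extract_key_region(sc, scene_plane, cfg)
  h <- height_above_ground(sc, scene_plane)
  expect_equal(n_points(key), sum(h >= 0.2 & h <= 1.6))
  # full-range window is the identity
  all_cfg <- match_config(key_region = c(-10, 10))
  expect_equal(n_points(extract_key_region(sc, scene_plane, all_cfg)),
               n_points(sc))
  above <- match_config(key_region = c(50, 60))
  expect_error(extract_key_region(sc, scene_plane, above),
               class = "treereg_empty_region")
})

test_that("the branch ring selects by perpendicular distance to the axis", {
  sc <- stub_scene()
  cfg <- match_config()
  ring <- segment_branch_ring(sc, scene_trunk, cfg)
  d <- sqrt(rowSums(ring$points[, 1:2, drop = FALSE]^2))
  expect_true(all(d >= cfg$ring_min - 1e-12 & d <= cfg$ring_max + 1e-12))
  expect_true(all(ring$labels == "branch"))
  # closed-form point-to-line distances on random points
  set.seed(13)
  P <- matrix(runif(300, -1, 1), ncol = 3)
  a <- c(0.3, -0.2, 0.1); dir <- c(0.1, 0.2, 0.97); dir <- dir / sqrt(sum(dir^2))
  got <- treereg:::point_line_dist(P, a, dir)
  want <- apply(P, 1, function(p) {
    w <- p - a
    sqrt(sum((w - sum(w * dir) * dir)^2))
  })
  expect_lt(max(abs(got - want)), 1e-12)
})

test_that("candidate filtering finds clean stubs with accurate radii", {
  sc <- stub_scene()
  cfg <- match_config(cluster_size = c(40, 5000), cyl_n_iter = 1500)
  ring <- segment_branch_ring(sc, scene_trunk, cfg)
  segs <- filter_candidates(ring, scene_trunk, scene_plane, cfg, seed = 1)
  expect_length(segs, 4)
  ids <- vapply(segs, `[[`, 1L, "gt_branch_id")
  radii_true <- c(0.008, 0.010, 0.012, 0.016)[ids]
  expect_true(all(abs(vapply(segs, `[[`, 1, "r") - radii_true) < 1.5e-3))
})

test_that("the cluster size gate and inlier-ratio gate drop bad candidates", {
  sc <- stub_scene()
  cfg_big <- match_config(cluster_size = c(5000, 10000))
  ring <- segment_branch_ring(sc, scene_trunk, cfg_big)
  expect_length(filter_candidates(ring, scene_trunk, scene_plane, cfg_big, 1), 0)
  # a wide, thin planar patch in the ring: no branch-scale cylinder can
  # cover 30% of it
  set.seed(14)
  patch <- point_cloud(cbind(0.08 + runif(500, 0, 0.2),
                             runif(500, 0, 0.2),
                             0.5 + rnorm(500, 0, 0.001)))
  cfg <- match_config(cluster_size = c(40, 5000))
  segs <- filter_candidates(patch, scene_trunk, scene_plane, cfg, seed = 2)
  expect_length(segs, 0)
})

test_that("branch features fold the angle and use the point centroid height", {
  trunk <- scene_trunk
  perp <- cylinder3d(c(0.1, 0, 1), c(1, 0, 0), 0.01)
  pts <- matrix(c(0.1, 0, 1), 1)
  f <- branch_features(pts, perp, trunk, scene_plane)
  expect_equal(f$theta, pi / 2)
  par_up <- cylinder3d(c(0.1, 0, 1), c(0, 0, 1), 0.01)
  par_dn <- cylinder3d(c(0.1, 0, 1), c(0, 0, -1), 0.01)
  expect_equal(branch_features(pts, par_up, trunk, scene_plane)$theta, 0)
  expect_equal(branch_features(pts, par_dn, trunk, scene_plane)$theta, 0)
  expect_equal(f$h, 1.0)
})

test_that("the threshold gate is strict in all three features", {
  cfg <- match_config()
  expect_true(threshold_gate(0.002, 5 * pi / 180, 0.020, cfg))
  expect_false(threshold_gate(0.006, 1 * pi / 180, 0.001, cfg))
  expect_false(threshold_gate(0.005, 15 * pi / 180, 0.050, cfg))  # boundary
})

test_that("the fused residual reproduces its closed forms", {
  cfg <- match_config()
  even <- pair_score(0.5 * cfg$tol_r, 0.5 * cfg$tol_theta, 0.5 * cfg$tol_h, cfg)
  expect_equal(c(even$w_r, even$w_theta, even$w_h), rep(1 / 3, 3))
  expect_equal(even$score, 0.5)
  mixed <- pair_score(0.1 * cfg$tol_r, 0.5 * cfg$tol_theta, 0.5 * cfg$tol_h, cfg)
  expect_equal(mixed$score, 0.25032, tolerance = 1e-4)
  expect_equal(c(mixed$w_r, mixed$w_theta, mixed$w_h),
               c(0.62420, 0.18790, 0.18790), tolerance = 1e-4)
  tiny <- pair_score(0, 0, 0, cfg)
  expect_lt(tiny$score, 1e-5)
  expect_error(pair_score(cfg$tol_r, 0, 0, cfg), class = "treereg_contract_error")
})

test_that("weights always sum to one and scoring is scale-equivariant", {
  set.seed(15)
  cfg <- match_config()
  for (i in 1:200) {
    d <- runif(3) * c(cfg$tol_r, cfg$tol_theta, cfg$tol_h) * 0.999
    s <- pair_score(d[1], d[2], d[3], cfg)
    expect_equal(s$w_r + s$w_theta + s$w_h, 1, tolerance = 1e-9)
    # rescale one residual together with its tolerance: score unchanged
    cfg2 <- match_config(tol_r = cfg$tol_r * 7)
    s2 <- pair_score(d[1] * 7, d[2], d[3], cfg2)
    expect_equal(s2$score, s$score, tolerance = 1e-12)
  }
  for (x in c(0.1, 0.5, 0.9)) {
    s <- pair_score(x * cfg$tol_r, x * cfg$tol_theta, x * cfg$tol_h, cfg)
    expect_identical(s$score, x)  # equal-residual closed form
  }
})

mk_seg <- function(r, theta, h, inliers, id = NA_integer_) {
  structure(list(cluster = cluster3d(seq_len(inliers)),
                 cylinder = cylinder3d(c(0.1, 0, h), c(1, 0, 0), r),
                 r = r, theta = theta, h = h, inlier_count = inliers,
                 gt_branch_id = id), class = "branch_segment")
}

test_that("matching self-pairs succeeds and disjoint features fail", {
  s <- mk_seg(0.01, 1.2, 0.8, 120, 1L)
  res <- match_branches(list(s), list(s))
  expect_true(res$success)
  expect_lt(res$best$score, 1e-5)
  far <- mk_seg(0.02, 0.3, 2.0, 90, 2L)
  expect_false(match_branches(list(s), list(far))$success)
})

test_that("greedy assignment matches exhaustive search on a 3x3 instance", {
  cfg <- match_config()
  S <- list(mk_seg(0.0100, 1.20, 0.80, 100, 1L),
            mk_seg(0.0140, 0.95, 1.10, 140, 2L),
            mk_seg(0.0180, 1.40, 1.40, 90, 3L))
  T_ <- list(mk_seg(0.0102, 1.22, 0.81, 110, 1L),
             mk_seg(0.0141, 0.96, 1.12, 150, 2L),
             mk_seg(0.0178, 1.39, 1.39, 80, 3L))
  res <- match_branches(S, T_, cfg)
  expect_true(res$success)
  # oracle: all 3! one-to-one assignments, minimize total score of gated pairs
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  cost <- function(p) sum(vapply(1:3, function(i) {
    d <- c(abs(S[[i]]$r - T_[[p[i]]]$r), abs(S[[i]]$theta - T_[[p[i]]]$theta),
           abs(S[[i]]$h - T_[[p[i]]]$h))
    if (!threshold_gate(d[1], d[2], d[3], cfg)) return(Inf)
    pair_score(d[1], d[2], d[3], cfg)$score
  }, 1))
  best_perm <- perms[[which.min(vapply(perms, cost, 1))]]
  got <- vapply(res$retained, function(p) p$tgt_idx, 1L)[
    order(vapply(res$retained, function(p) p$src_idx, 1L))]
  expect_equal(got, best_perm)
  # best pair carries the maximum combined inlier count among accepted
  inl <- vapply(res$retained, `[[`, 1, "inliers")
  expect_equal(res$best$inliers, max(inl))
})

test_that("matching is symmetric in the scan roles", {
  S <- list(mk_seg(0.0100, 1.20, 0.80, 100, 1L),
            mk_seg(0.0140, 0.95, 1.10, 140, 2L))
  T_ <- list(mk_seg(0.0101, 1.21, 0.82, 90, 1L),
             mk_seg(0.0139, 0.94, 1.09, 70, 2L))
  ab <- match_branches(S, T_)
  ba <- match_branches(T_, S)
  expect_equal(ab$best$src$gt_branch_id, ba$best$tgt$gt_branch_id)
  expect_equal(ab$best$tgt$gt_branch_id, ba$best$src$gt_branch_id)
})
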