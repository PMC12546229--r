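test_that("rotation angles follow the axis-angle closed form", {
  expect_equal(rotation_angle(diag(3)), 0)
  Rz90 <- rotation_block(rt_rot_z_about(pi / 2))
  expect_equal(rotation_angle(Rz90), pi / 2)
  set.seed(22)
  for (i in 1:20) {
    ax <- rnorm(3)
    R <- rodrigues_R(ax, 0.3)
    expect_equal(rotation_angle(R), 0.3, tolerance = 1e-9)
  }
  expect_error(rotation_angle(matrix(1, 3, 3)), class = "treereg_contract_error")
})

test_that("rotation error is exact for composed z-rotations and symmetric", {
  R1 <- rotation_block(rt_rot_z_about(0.1))
  R2 <- rotation_block(rt_rot_z_about(0.1 + 0.00193))
  expect_equal(rotation_error(R1, R2, unit = "mrad"), 1.93, tolerance = 1e-6)
  expect_equal(rotation_error(R1, R1), 0)
  set.seed(23)
  for (i in 1:30) {
    A <- rodrigues_R(rnorm(3), runif(1, 0, pi))
    B <- rodrigues_R(rnorm(3), runif(1, 0, pi))
    expect_equal(rotation_error(A, B), rotation_error(B, A), tolerance = 1e-9)
    # quaternion-distance oracle: angle = 2*acos(|<qa, qb>|)
    q <- function(R) {
      tr <- sum(diag(R))
      w <- sqrt(max(0, 1 + tr)) / 2
      v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
        (4 * max(w, 1e-12))
      c(w, v)
    }
    qa <- q(A); qb <- q(B)
    ang <- 2 * acos(min(1, abs(sum(qa * qb) /
                                 sqrt(sum(qa^2) * sum(qb^2)))))
    expect_equal(rotation_error(A, B), ang, tolerance = 1e-6)
    expect_gte(rotation_error(A, B), 0)
  }
})

test_that("translation error is the Euclidean norm", {
  expect_equal(translation_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(translation_error(c(0.003, 0.004, 0), c(0, 0, 0), unit = "mm"), 5)
  set.seed(24)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(translation_error(a, b), sqrt(sum((a - b)^2)),
                 tolerance = 1e-12)
  }
})

test_that("pointwise error equals the per-point loop oracle", {
  set.seed(25)
  pc <- point_cloud(matrix(runif(300, -2, 2), ncol = 3))
  Ta <- rigid_transform(unclass(rt_translation(runif(3))) %*%
                          unclass(rt_rot_z_about(runif(1, -1, 1), runif(2))))
  Tb <- rigid_transform(unclass(rt_translation(runif(3))) %*%
                          unclass(rt_rot_z_about(runif(1, -1, 1), runif(2))))
  got <- pointwise_error(pc, Ta, Tb)
  Ra <- rotation_block(Ta); ta <- translation_vec(Ta)
  Rb <- rotation_block(Tb); tb <- translation_vec(Tb)
  ds <- vapply(seq_len(n_points(pc)), function(i) {
    p <- pc$points[i, ]
    sqrt(sum(((Ra %*% p + ta) - (Rb %*% p + tb))^2))
  }, 1)
  expect_equal(got$e_p, mean(ds), tolerance = 1e-12)
  expect_lte(got$e_p, sum(got$e_p_xyz) + 1e-12)
  expect_equal(pointwise_error(pc, Ta, Ta)$e_p, 0)
  # shared rotation: pointwise error collapses to the translation distance
  Tshift <- rigid_transform(unclass(rt_translation(c(0.005, 0, 0))) %*%
                              unclass(Ta))
  pw <- pointwise_error(pc, Tshift, Ta, unit = "mm")
  expect_equal(pw$e_p, 5, tolerance = 1e-9)
  expect_equal(pw$e_p_xyz, c(5, 0, 0), tolerance = 1e-9)
})

test_that("match success requires the ground-truth correspondence", {
  seg <- function(id) structure(list(cluster = cluster3d(1:10),
    cylinder = cylinder3d(c(0.1, 0, 1), c(1, 0, 0), 0.01), r = 0.01,
    theta = 1, h = 1, inlier_count = 10, gt_branch_id = id),
    class = "branch_segment")
  good <- match_branches(list(seg(7L)), list(seg(7L)))
  expect_true(match_success(good))
  expect_true(match_success(good, cbind(7L, 7L)))
  expect_false(match_success(good, cbind(7L, 8L)))
  none <- structure(list(best = NULL, retained = list(), success = FALSE),
                    class = "match_result")
  expect_false(match_success(none))
})

test_that("completeness is a directional coverage fraction", {
  g <- expand.grid(x = seq(0, 0.95, by = 0.05), y = seq(0, 0.95, by = 0.05))
  ref <- point_cloud(cbind(g$x, g$y, 0))
  expect_equal(completeness(ref, ref), 1.0)
  half <- subset_cloud(ref, seq(1, n_points(ref), by = 2))
  expect_equal(completeness(half, ref, thresh = 0.005), 0.5)
  # indexed NN equals brute force
  set.seed(26)
  test_c <- point_cloud(matrix(runif(300, 0, 1), ncol = 3))
  ref_c <- point_cloud(matrix(runif(600, 0, 1), ncol = 3))
  nn <- bf_nn(ref_c$points, test_c$points)
  for (th in c(0.02, 0.05, 0.1))
    expect_equal(completeness(test_c, ref_c, th), mean(nn[, 2] <= th))
  # monotone in the threshold and in the test set
  expect_lte(completeness(test_c, ref_c, 0.02), completeness(test_c, ref_c, 0.05))
  bigger <- point_cloud(rbind(test_c$points, matrix(runif(90, 0, 1), ncol = 3)))
  expect_lte(completeness(test_c, ref_c, 0.05), completeness(bigger, ref_c, 0.05))
})

test_that("structural parameters recover the generator's geometry", {
  spec <- quick_spec(seed = 31)
  tree <- generate_tree(spec)
  pl <- ground_plane(c(0, 0, 1), 0)
  noground <- subset_cloud(tree, tree$labels != "ground")
  sp <- structural_params(noground, pl, seed = 1)
  d25 <- 100 * spec$basal_trunk_diameter * (1 - spec$trunk_taper * 0.25)
  expect_lt(abs(sp$basal_trunk_diameter_cm - d25), 0.2)
  btab <- attr(tree, "branches")
  apex <- max(spec$height,
              max(btab$insertion_height + btab$length * cos(btab$insertion_angle)))
  expect_lt(abs(sp$tree_height_cm - 100 * apex), 100 * 3 * spec$noise_sigma + 0.5)
  n_thick <- sum(2 * btab$basal_radius > 0.01)
  expect_equal(sp$n_primary_branches, n_thick)
  expect_gt(sp$avg_branch_diameter_cm, 1)
})
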