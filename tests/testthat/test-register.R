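test_that("the yaw-about-O matrix equals its symbolic factorization", {
  set.seed(16)
  for (i in 1:200) {
    a <- runif(1, -pi, pi); O <- runif(2, -3, 3)
    T1 <- rt_rot_z_about(a, O)
    M <- unclass(rt_translation(c(O, 0))) %*% unclass(rt_rot_z_about(a)) %*%
      unclass(rt_translation(-c(O, 0)))
    expect_lt(max(abs(M - unclass(T1))), 1e-12)
    # the vertical line through O is fixed for any z
    for (z in c(-1, 0, 2.5)) {
      p <- transform_points(matrix(c(O, z), 1), T1)
      expect_lt(max(abs(p - c(O, z))), 1e-9)
    }
  }
})

test_that("rotation recovery solves the constructed inverse problem", {
  trunk <- cylinder3d(c(0, 0, 0), c(0, 0, 1), 0.03)
  # the rotation center must lie on the source projected axis for the
  # intersection construction to recover it exactly
  b_src <- cylinder3d(c(0.4, -0.2, 1), c(0.8, 0.2, 0.3), 0.01)
  Tst <- rt_rot_z_about(pi / 6, c(0.4, -0.2))   # 30 deg about (0.4, -0.2)
  R <- rotation_block(Tst)
  b_tgt <- cylinder3d(as.vector(R %*% b_src$axis_point) + translation_vec(Tst),
                      as.vector(R %*% b_src$axis_dir), 0.01)
  trunk_tgt <- cylinder3d(as.vector(R %*% trunk$axis_point) + translation_vec(Tst),
                          c(0, 0, 1), 0.03)
  rot <- rotation_from_branches(b_src, b_tgt, trunk, trunk_tgt)
  expect_equal(rot$alpha, pi / 6, tolerance = 1e-6)
  expect_lt(max(abs(rot$O - c(0.4, -0.2))), 1e-6)
})

test_that("identical matched axes give the identity yaw", {
  trunk <- cylinder3d(c(0, 0, 0), c(0, 0, 1), 0.03)
  b <- cylinder3d(c(0.1, 0, 1), c(1, 0, 0.2), 0.01)
  rot <- rotation_from_branches(b, b, trunk)
  expect_equal(rot$alpha, 0)
  expect_transform_equal(rot$T1, rt_identity())
})

test_that("vertical matched branch axes raise a coarse failure", {
  trunk <- cylinder3d(c(0, 0, 0), c(0, 0, 1), 0.03)
  b <- cylinder3d(c(0.1, 0, 1), c(0, 0, 1), 0.01)
  expect_error(rotation_from_branches(b, b, trunk),
               class = "treereg_coarse_failure")
})

trunk_slab_cloud <- function(shift = c(0, 0, 0), sigma = 0, seed = 1) {
  P <- cyl_points(radius = 0.03, len = 1.2, base = c(0, 0, 0.05),
                  spacing = 0.006, sigma = sigma, seed = seed)
  point_cloud(sweep(P, 2, shift, `+`))
}

test_that("trunk-center translation recovers identity and known shifts", {
  pl <- ground_plane(c(0, 0, 1), 0)
  src <- trunk_slab_cloud()
  tra <- translation_from_trunks(src, src, pl, pl, seed = 1)
  expect_lt(sqrt(sum((tra$G_tgt - tra$G_src)^2)), 5e-4)
  shift <- c(1, 2, 0.5)
  tgt <- trunk_slab_cloud(shift = shift)
  pl_t <- ground_plane(c(0, 0, 1), -0.5)  # target ground at z = 0.5
  tra2 <- translation_from_trunks(src, tgt, pl, pl_t, seed = 1)
  expect_lt(max(abs(translation_vec(tra2$T2) - shift)), 1e-3)
})

test_that("composition order is coarse = T2 T1 and full = Tf Tc", {
  T1 <- rt_rot_z_about(0.4, c(0.2, -0.1))
  T2 <- rt_translation(c(0.5, -0.3, 0.1))
  Tc <- rigid_transform(unclass(T2) %*% unclass(T1))
  set.seed(17)
  P <- matrix(runif(60, -1, 1), ncol = 3)
  expect_equal(transform_points(transform_points(P, T1), T2),
               transform_points(P, Tc))
  Tf <- rt_rot_z_about(-0.1, c(0, 0))
  T_full <- rigid_transform(unclass(Tf) %*% unclass(Tc))
  expect_equal(transform_points(transform_points(P, Tc), Tf),
               transform_points(P, T_full))
})

test_that("trimmed ICP is exact on identical and rigidly moved clouds", {
  set.seed(18)
  P <- matrix(runif(1500, 0, 1), ncol = 3)
  pc <- point_cloud(P)
  res <- trimmed_icp(pc, pc)
  expect_transform_equal(res$transform, rt_identity(), tol = 1e-9)
  expect_lte(res$n_iter, 2)
  # known small motion: Rz(0.05 rad) + (10, 5, 2) mm
  Tm <- rigid_transform(unclass(rt_translation(c(0.010, 0.005, 0.002))) %*%
                          unclass(rt_rot_z_about(0.05)))
  moved <- apply_transform(pc, Tm)
  res2 <- trimmed_icp(pc, moved, icp_config(max_corr_dist = 0.2))
  eR <- rotation_error(rotation_block(res2$transform), rotation_block(Tm))
  expect_lt(eR, 1e-3)
  expect_lt(translation_error(translation_vec(res2$transform),
                              translation_vec(Tm)), 5e-4)
})

test_that("one rigid solve equals the closed-form SVD solution", {
  set.seed(19)
  A <- matrix(runif(90, -1, 1), ncol = 3)
  Tm <- rigid_transform(unclass(rt_translation(c(0.2, -0.1, 0.3))) %*%
                          unclass(rt_rot_z_about(0.7, c(0.1, 0.4))))
  B <- transform_points(A, Tm)
  got <- treereg:::.rigid_solve(A, B)
  # independent oracle: Kabsch written out longhand
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(A - matrix(ca, nrow(A), 3, TRUE)) %*% (B - matrix(cb, nrow(B), 3, TRUE))
  sv <- svd(H)
  R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  expect_lt(max(abs(rotation_block(got) - R)), 1e-9)
  expect_lt(max(abs(translation_vec(got) - (cb - as.vector(R %*% ca)))), 1e-9)
  expect_transform_equal(got, Tm, tol = 1e-9)
})

test_that("the trimmed RMS sequence never increases", {
  set.seed(20)
  P <- cyl_points(radius = 0.05, len = 0.6, spacing = 0.01, sigma = 0.002,
                  seed = 20)
  Q <- cyl_points(radius = 0.05, len = 0.6, spacing = 0.01, sigma = 0.002,
                  seed = 21)
  Tm <- rigid_transform(unclass(rt_translation(c(0.01, -0.02, 0.005))) %*%
                          unclass(rt_rot_z_about(0.04)))
  res <- trimmed_icp(point_cloud(P), apply_transform(point_cloud(Q), Tm),
                     icp_config(max_corr_dist = 0.2))
  expect_true(all(diff(res$rms_history) <= 1e-15))
})

test_that("ICP degenerate inputs raise fine failures", {
  a <- point_cloud(matrix(runif(30), ncol = 3))
  b <- point_cloud(matrix(runif(30), ncol = 3) + 10)  # beyond max_corr_dist
  expect_error(trimmed_icp(a, b), class = "treereg_fine_failure")
})

test_that("branch extraction removes the trunk and fails on trunk-only input", {
  sc_trunk <- point_cloud(cyl_points(radius = 0.03, len = 1, spacing = 0.01))
  trunk <- cylinder3d(c(0, 0, 0), c(0, 0, 1), 0.03)
  expect_error(extract_branch_only(sc_trunk, trunk),
               class = "treereg_fine_failure")
  far <- point_cloud(rbind(cyl_points(radius = 0.03, len = 1, spacing = 0.01),
                           matrix(c(0.3, 0, 0.5), 1)))
  kept <- extract_branch_only(far, trunk)
  expect_equal(n_points(kept), 1)
  expect_error(extract_branch_only(far, trunk, margin = Inf),
               class = "treereg_fine_failure")
})

test_that("transform application honors identity, inverse and translation", {
  set.seed(21)
  pc <- point_cloud(matrix(runif(90, -2, 2), ncol = 3),
                    labels = sample(c("trunk", "branch"), 30, TRUE))
  expect_equal(apply_transform(pc, rt_identity())$points, pc$points)
  Tm <- rigid_transform(unclass(rt_translation(c(0.3, 0.1, -0.2))) %*%
                          unclass(rt_rot_z_about(1.1, c(0.5, 0.5))))
  back <- apply_transform(apply_transform(pc, Tm), rt_inverse(Tm))
  expect_lt(max(abs(back$points - pc$points)), 1e-12)
  expect_identical(back$labels, pc$labels)
  tr <- apply_transform(pc, rt_translation(c(1, 2, 3)))
  expect_equal(tr$points, sweep(pc$points, 2, c(1, 2, 3), `+`))
})
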