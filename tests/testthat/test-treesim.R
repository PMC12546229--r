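test_that("a noiseless trunk-only tree lies exactly on its analytic surface", {
  spec <- tree_spec(n_branches = 0, noise_sigma = 0, surface_sampling = 0.01,
                    ground_extent = 0.2, seed = 1)
  tree <- generate_tree(spec)
  tk <- subset_cloud(tree, tree$labels == "trunk")
  r0 <- spec$basal_trunk_diameter / 2
  r_at <- r0 * (1 - spec$trunk_taper * tk$points[, 3])
  radial <- sqrt(rowSums(tk$points[, 1:2, drop = FALSE]^2))
  expect_lt(max(abs(radial - r_at)), 1e-9)
})

test_that("every requested branch id is present and labeled", {
  tree <- generate_tree(quick_spec(seed = 2))
  ids <- sort(unique(tree$branch_id[!is.na(tree$branch_id)]))
  expect_equal(ids, 1:11)
  expect_setequal(unique(tree$labels), c("trunk", "branch", "ground"))
  expect_true(all(is.na(tree$branch_id[tree$labels != "branch"])))
})

test_that("the fitted trunk radius matches the analytic taper at 0.25 m", {
  spec <- quick_spec(seed = 3)
  tree <- generate_tree(spec)
  h <- tree$points[, 3]
  slab <- subset_cloud(tree, tree$labels == "trunk" & h >= 0.2 & h <= 0.3)
  cyl <- ransac_cylinder(slab, dist_thresh = 0.005, n_iter = 2000, seed = 1,
                         axis_prior = c(0, 0, 1))
  r_true <- spec$basal_trunk_diameter / 2 * (1 - spec$trunk_taper * 0.25)
  expect_lt(abs(cyl$radius - r_true), 1e-3)
})

test_that("no branch point lies below ground; taper is monotone", {
  tree <- generate_tree(tree_spec(noise_sigma = 0, surface_sampling = 0.008,
                                  seed = 4))
  br <- subset_cloud(tree, tree$labels == "branch")
  expect_true(all(br$points[, 3] > 0))
  tk <- subset_cloud(tree, tree$labels == "trunk")
  radial <- sqrt(rowSums(tk$points[, 1:2, drop = FALSE]^2))
  ord <- order(tk$points[, 3])
  expect_true(all(diff(radial[ord]) <= 1e-9))
})

test_that("infeasible specs are rejected", {
  expect_error(tree_spec(branch_insertion_height_range = c(-0.1, 2)),
               class = "treereg_spec_error")
  expect_error(tree_spec(height = 2, branch_insertion_height_range = c(0.3, 2.8)),
               class = "treereg_spec_error")
  expect_error(tree_spec(trunk_taper = 0.5), class = "treereg_spec_error")
  expect_error(tree_spec(branch_diameter_range = c(0.03, 0.01)),
               class = "treereg_spec_error")
})

test_that("frontface with no grazing keeps the facing half of a cylinder", {
  spec <- tree_spec(n_branches = 0, noise_sigma = 0, surface_sampling = 0.008,
                    ground_extent = 0.2, seed = 5)
  tree <- generate_tree(spec)
  pair <- simulate_two_stations(tree, grazing = 0, seed = 5)
  # target is in the tree frame: its visible trunk fraction is ~ half
  frac <- sum(pair$target$labels == "trunk") / sum(tree$labels == "trunk")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("the ground truth maps source branches onto target branches", {
  spec <- tree_spec(noise_sigma = 0, surface_sampling = 0.006, seed = 6)
  tree <- generate_tree(spec)
  pair <- simulate_two_stations(tree, seed = 6)
  moved <- apply_transform(pair$source, pair$T_gt)
  for (id in pair$correspondence[, 1][1:3]) {
    ms <- moved$points[!is.na(moved$branch_id) & moved$branch_id == id, , drop = FALSE]
    tt <- pair$target$points[!is.na(pair$target$branch_id) &
                               pair$target$branch_id == id, , drop = FALSE]
    # where both stations see the same branch, shared silhouette-band points
    # coincide exactly in the noiseless case
    nn <- bf_nn(ms[seq_len(min(200, nrow(ms))), , drop = FALSE], tt)
    expect_lt(min(nn[, 2]), 1e-9)
  }
})

test_that("opposed stations share a small but nonzero silhouette band", {
  spec <- tree_spec(n_branches = 0, noise_sigma = 0, surface_sampling = 0.008,
                    ground_extent = 0.2, seed = 7)
  tree <- generate_tree(spec)
  s1 <- c(2.3, 0, 1.5); s2 <- c(-2.3, 0, 1.5)
  vis <- function(s) {
    V <- sweep(-tree$points, 2, s, `+`)
    rowSums(tree$normals * V) / sqrt(rowSums(V^2)) > -sin(5 * pi / 180)
  }
  tk <- tree$labels == "trunk"
  shared <- mean(vis(s1)[tk] & vis(s2)[tk])
  expect_gt(shared, 0.001)
  expect_lt(shared, 0.15)
  # low-overlap regime: each scan sees well under 60% of the tree
  expect_lt(mean(vis(s1)), 0.60)
  expect_lt(mean(vis(s2)), 0.60)
})

test_that("generation and simulation are bit-reproducible", {
  a <- generate_tree(quick_spec(seed = 8))
  b <- generate_tree(quick_spec(seed = 8))
  expect_identical(a$points, b$points)
  pa <- simulate_two_stations(a, seed = 9)
  pb <- simulate_two_stations(b, seed = 9)
  expect_identical(pa$source$points, pb$source$points)
  expect_identical(unclass(pa$T_gt), unclass(pb$T_gt))
})

test_that("fixture suites vary within the documented ranges and serialize", {
  dir <- withr::local_tempdir()
  base <- tree_spec(surface_sampling = 0.01, ground_extent = 0.2,
                    ground_sampling = 0.02)
  suite <- make_fixture_suite(6, base, seed = 0, dir = dir)
  nb <- vapply(suite, function(p) p$spec$n_branches, 1)
  expect_true(all(nb >= 8 & nb <= 18))
  expect_gt(length(unique(nb)), 1)
  # manifest ground truth round-trips exactly through the JSON writer
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man), 6)
  gt1 <- read_transform_json(file.path(dir, man$gt[1]))
  expect_equal(as.vector(unclass(gt1)), as.vector(unclass(suite[[1]]$T_gt)), tolerance = 0)
  # and the serialized clouds re-read bit-exactly
  src1 <- read_cloud(file.path(dir, man$source[1]))
  expect_identical(src1$points, suite[[1]]$source$points)
  # reruns are bit-identical
  suite2 <- make_fixture_suite(6, base, seed = 0)
  expect_identical(suite2[[3]]$source$points, suite[[3]]$source$points)
})

test_that("the hpr visibility model also yields two plausible low-overlap scans", {
  spec <- tree_spec(surface_sampling = 0.008, ground_extent = 0.2, seed = 10)
  tree <- generate_tree(spec)
  pair <- simulate_two_stations(tree, occlusion = "hpr", seed = 10)
  expect_gt(n_points(pair$source), 1000)
  expect_lt(sum(pair$target$labels == "trunk"),
            0.8 * sum(tree$labels == "trunk"))
})
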