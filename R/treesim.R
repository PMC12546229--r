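# Procedural tall-spindle tree generator and two-station scan simulator.
# Surfaces are sampled frusta with analytic outward normals; the normals
# drive the per-station self-occlusion model and every point carries its
# semantic label and branch id, so the simulator doubles as the oracle for
# the whole pipeline.

#' Tree specification
#'
#' Geometry of a synthetic tall-spindle tree. Defaults emulate a dormant
#' 5-7-year-old high-density apple tree: ~3.3 m tall, 6.2 cm basal trunk
#' diameter, 11 primary branches of 1.4-3.3 cm diameter inserted between
#' 0.3 and 2.8 m at 50-90 degrees from the trunk axis, ~2 mm surface
#' sampling and 2 mm Gaussian sensor noise.
#'
#' @param height tree height (m).
#' @param basal_trunk_diameter trunk diameter at the base (m).
#' @param trunk_taper fractional radius loss per meter of height.
#' @param n_branches number of primary branches.
#' @param branch_diameter_range basal branch diameter range (m).
#' @param branch_insertion_height_range insertion heights (m).
#' @param branch_insertion_angle_range insertion angles from the trunk axis
#'   (degrees; 90 = horizontal).
#' @param branch_length_range branch lengths (m).
#' @param azimuth_jitter jitter around evenly spread branch azimuths (degrees).
#' @param branch_curvature total in-branch bend (radians; 0 = straight frusta).
#' @param surface_sampling surface sampling spacing (m).
#' @param ground_sampling ground-disc sampling spacing (m); ground density
#'   only feeds the plane fit, so it defaults to twice the surface spacing.
#' @param noise_sigma isotropic Gaussian sensor noise (m).
#' @param ground_extent radius of the ground disc (m).
#' @param seed RNG seed; generation is bit-reproducible.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(height = 3.3, basal_trunk_diameter = 0.062,
                      trunk_taper = 0.25, n_branches = 11,
                      branch_diameter_range = c(0.014, 0.033),
                      branch_insertion_height_range = c(0.3, 2.8),
                      branch_insertion_angle_range = c(50, 90),
                      branch_length_range = c(0.35, 0.8),
                      azimuth_jitter = 20, branch_curvature = 0,
                      surface_sampling = 0.002,
                      ground_sampling = 2 * surface_sampling,
                      noise_sigma = 0.002, ground_extent = 0.6, seed = 1) {
  spec <- structure(as.list(environment()), class = "tree_spec")
  if (height <= 0 || basal_trunk_diameter <= 0 || surface_sampling <= 0 ||
      ground_sampling <= 0 || ground_extent <= 0)
    stop_treereg("tree dimensions and sampling spacings must be positive",
                 "treereg_spec_error")
  if (trunk_taper < 0 || trunk_taper * height >= 0.95)
    stop_treereg("trunk taper must keep the top radius positive",
                 "treereg_spec_error")
  if (n_branches < 0) stop_treereg("n_branches must be >= 0", "treereg_spec_error")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(branch_diameter_range) || !rng_ok(branch_insertion_height_range) ||
      !rng_ok(branch_insertion_angle_range) || !rng_ok(branch_length_range))
    stop_treereg("branch parameter ranges must be well-ordered", "treereg_spec_error")
  if (n_branches > 0 && (branch_insertion_height_range[1] <= 0 ||
                         branch_insertion_height_range[2] > height))
    stop_treereg("branch insertion heights must lie within (0, tree height]",
                 "treereg_spec_error")
  if (noise_sigma < 0) stop_treereg("noise_sigma must be >= 0", "treereg_spec_error")
  spec
}

#' @export
print.tree_spec <- function(x, ...) {
  cat(sprintf("<tree_spec: %.2f m tall, trunk %.1f cm, %d branches, noise %.1f mm, seed %d>\n",
              x$height, 100 * x$basal_trunk_diameter, x$n_branches,
              1000 * x$noise_sigma, x$seed))
  invisible(x)
}

# Sample the surface of a (possibly gently curved) frustum. Returns points,
# outward normals and the per-ring axis stations. Phases are drawn from the
# active RNG stream.
.sample_frustum <- function(start, dir, len, r0, r1, ds, curvature = 0) {
  dir <- unit_vec(dir)
  s <- seq(0, len, by = ds)
  nr <- length(s)
  radii <- r0 + (r1 - r0) * s / len
  drds <- (r1 - r0) / len
  basis <- .plane_basis(dir)
  if (curvature != 0) {
    bend_axis <- basis$e1
    dirs <- lapply(curvature * s / len, function(a) .rodrigues(dir, bend_axis, a))
    centers <- matrix(start, nr, 3, byrow = TRUE)
    if (nr > 1) {
      steps <- do.call(rbind, dirs[-nr]) * ds
      centers[-1, ] <- centers[-1, , drop = FALSE] + apply(steps, 2, cumsum)
    }
  } else {
    dirs <- rep(list(dir), nr)
    centers <- matrix(start, nr, 3, byrow = TRUE) + outer(s, dir)
  }
  nc <- pmax(8L, ceiling(2 * pi * radii / ds))
  phases <- runif(nr, 0, 2 * pi)
  ring <- rep.int(seq_len(nr), nc)
  within <- sequence(nc)
  ang <- phases[ring] + 2 * pi * (within - 1) / nc[ring]
  D <- do.call(rbind, dirs)[ring, , drop = FALSE]
  B1 <- matrix(0, length(ring), 3); B2 <- B1
  for (i in seq_len(nr)) {
    b <- .plane_basis(dirs[[i]])
    sel <- ring == i
    B1[sel, ] <- matrix(b$e1, sum(sel), 3, byrow = TRUE)
    B2[sel, ] <- matrix(b$e2, sum(sel), 3, byrow = TRUE)
  }
  U <- B1 * cos(ang) + B2 * sin(ang)
  P <- centers[ring, , drop = FALSE] + U * radii[ring]
  N <- U - drds * D
  N <- N / sqrt(rowSums(N^2))
  list(points = P, normals = N)
}

.rodrigues <- function(v, k, a) {
  k <- unit_vec(k)
  v * cos(a) + pracma_cross(k, v) * sin(a) + k * sum(k * v) * (1 - cos(a))
}

#' Generate a labeled synthetic tree cloud
#'
#' Tapered near-vertical trunk, straight (or gently curved) branch frusta
#' inserted at stratified heights and azimuths, and a ground disc at z = 0.
#' Every point carries a semantic label, a branch id where applicable, and
#' its analytic outward surface normal (pre-noise) for the visibility
#' model. Per-branch ground truth (insertion height, angle, azimuth, basal
#' radius, length) is attached as attribute `"branches"`.
#'
#' @param spec a [tree_spec()].
#' @return A labeled [point_cloud()] in the canonical tree frame (trunk on
#'   the z axis, ground at z = 0), with attributes `"spec"` and
#'   `"branches"`.
#' @export
generate_tree <- function(spec = tree_spec()) {
  stopifnot(inherits(spec, "tree_spec"))
  ds <- spec$surface_sampling
  r0 <- spec$basal_trunk_diameter / 2
  with_seed(spec$seed, {
    trunk <- .sample_frustum(c(0, 0, 0), c(0, 0, 1), spec$height,
                             r0, r0 * (1 - spec$trunk_taper * spec$height), ds)
    n <- spec$n_branches
    btab <- NULL
    br_pts <- list(); br_nrm <- list(); br_id <- list()
    if (n > 0) {
      hr <- spec$branch_insertion_height_range
      h_ins <- clamp(hr[1] + (seq_len(n) - 0.5 + runif(n, -0.3, 0.3)) / n * diff(hr),
                     hr[1], hr[2])
      az <- (seq_len(n) - 1) * 2 * pi / n +
        runif(n, -deg2rad(spec$azimuth_jitter), deg2rad(spec$azimuth_jitter))
      diam <- runif(n, spec$branch_diameter_range[1], spec$branch_diameter_range[2])
      ang <- deg2rad(runif(n, spec$branch_insertion_angle_range[1],
                           spec$branch_insertion_angle_range[2]))
      len <- runif(n, spec$branch_length_range[1], spec$branch_length_range[2])
      btab <- data.frame(branch_id = seq_len(n), insertion_height = h_ins,
                         azimuth = az, insertion_angle = ang,
                         basal_radius = diam / 2, length = len)
      for (i in seq_len(n)) {
        u <- c(cos(az[i]), sin(az[i]), 0)
        dir <- cos(ang[i]) * c(0, 0, 1) + sin(ang[i]) * u
        r_tr <- r0 * (1 - spec$trunk_taper * h_ins[i])
        start <- c(0, 0, h_ins[i]) + (r_tr - 0.005) * u
        fr <- .sample_frustum(start, dir, len[i], diam[i] / 2, 0.6 * diam[i] / 2,
                              ds, spec$branch_curvature)
        br_pts[[i]] <- fr$points
        br_nrm[[i]] <- fr$normals
        br_id[[i]] <- rep.int(i, nrow(fr$points))
      }
      btab$start_x <- vapply(seq_len(n), function(i) 0 +
        (r0 * (1 - spec$trunk_taper * h_ins[i]) - 0.005) * cos(az[i]), 1)
    }
    gs <- spec$ground_sampling
    gx <- seq(-spec$ground_extent, spec$ground_extent, by = gs)
    gg <- expand.grid(x = gx, y = gx)
    gg <- gg[gg$x^2 + gg$y^2 <= spec$ground_extent^2, ]
    ground_p <- cbind(gg$x, gg$y, 0)
    P <- rbind(trunk$points, do.call(rbind, c(br_pts, list(ground_p))))
    N <- rbind(trunk$normals,
               do.call(rbind, c(br_nrm, list(matrix(rep(c(0, 0, 1), nrow(ground_p)),
                                                    ncol = 3, byrow = TRUE)))))
    labels <- c(rep.int("trunk", nrow(trunk$points)),
                rep.int("branch", length(unlist(br_id))),
                rep.int("ground", nrow(ground_p)))
    branch_id <- c(rep.int(NA_integer_, nrow(trunk$points)), unlist(br_id),
                   rep.int(NA_integer_, nrow(ground_p)))
    if (spec$noise_sigma > 0)
      P <- P + matrix(rnorm(length(P), sd = spec$noise_sigma), ncol = 3)
    cloud <- point_cloud(P, labels = labels, branch_id = branch_id, normals = N)
    attr(cloud, "spec") <- spec
    attr(cloud, "branches") <- btab
    cloud
  })
}

# Range-image visibility: bin points by (azimuth, elevation) as seen from
# the station and keep, per bin, points within depth_tol of the nearest.
.depth_buffer_visible <- function(P, station, ang_res = deg2rad(0.3),
                                  depth_tol = 0.02) {
  V <- sweep(P, 2, station)
  rho <- sqrt(rowSums(V^2))
  az <- atan2(V[, 2], V[, 1])
  el <- asin(clamp(V[, 3] / rho, -1, 1))
  key <- paste(floor(az / ang_res), floor(el / ang_res))
  nearest <- stats::ave(rho, key, FUN = min)
  rho <= nearest + depth_tol
}

#' Simulate two opposed scan stations
#'
#' Places two stations at the given azimuths and distance from the trunk,
#' retains per station the points visible under the occlusion model
#' (`frontface`: outward analytic normal faces the scanner, exactly
#' reproducible; `hpr`: range-image hidden-point removal, harder fixtures),
#' and expresses the source scan in its own frame by applying the inverse
#' of a sampled ground-truth transform (yaw uniform on `(-pi, pi]`,
#' horizontal translation uniform in ±2 m, vertical in ±0.2 m; optional
#' small roll/pitch for robustness tests).
#'
#' @param tree a labeled tree cloud from [generate_tree()] (normals
#'   required).
#' @param distance station distance from the trunk (m).
#' @param azimuths station azimuths (rad), 180 degrees apart by default.
#' @param occlusion `"frontface"` or `"hpr"`.
#' @param grazing grazing-incidence tolerance of the frontface model
#'   (degrees): points are retained up to this angle past the exact
#'   silhouette, emulating the narrow transitional boundary both stations
#'   share on real scans (beam footprint and surface roughness return
#'   points slightly beyond 90 degree incidence). 0 gives the exact
#'   complementary split.
#' @param station_height scanner height above ground (m).
#' @param pose_jitter maximum roll/pitch of the sampled ground truth
#'   (degrees; 0 = exact 4-DoF).
#' @param seed RNG seed.
#' @return An object of class `scan_pair`: `source` and `target`
#'   [point_cloud()]s in their own frames, `T_gt` (maps source to target),
#'   `correspondence` (two-column matrix of branch-id pairs visible in
#'   both), `spec`, `stations`.
#' @export
simulate_two_stations <- function(tree, distance = 2.3, azimuths = c(0, pi),
                                  occlusion = c("frontface", "hpr"),
                                  grazing = 5, station_height = 1.5,
                                  pose_jitter = 0, seed = 0) {
  occlusion <- match.arg(occlusion)
  if (is.null(tree$normals))
    stop_treereg("the tree cloud lacks surface normals; regenerate with generate_tree()",
                 "treereg_spec_error")
  stations <- lapply(azimuths, function(a)
    c(distance * cos(a), distance * sin(a), station_height))
  visible <- lapply(stations, function(s) {
    if (occlusion == "frontface") {
      V <- sweep(-tree$points, 2, s, `+`)
      cosinc <- rowSums(tree$normals * V) / sqrt(rowSums(V^2))
      keep <- cosinc > -sin(deg2rad(grazing))
    } else {
      keep <- .depth_buffer_visible(tree$points, s)
    }
    if (!any(keep))
      stop_treereg("a station sees no points; check the spec", "treereg_sim_error")
    subset_cloud(tree, keep)
  })
  with_seed(seed, {
    yaw <- runif(1, -pi, pi)
    txy <- runif(2, -2, 2)
    tz <- runif(1, -0.2, 0.2)
    R <- rotation_block(rt_rot_z_about(yaw))
    if (pose_jitter > 0) {
      rp <- deg2rad(runif(2, -pose_jitter, pose_jitter))
      Rx <- rbind(c(1, 0, 0), c(0, cos(rp[1]), -sin(rp[1])), c(0, sin(rp[1]), cos(rp[1])))
      Ry <- rbind(c(cos(rp[2]), 0, sin(rp[2])), c(0, 1, 0), c(-sin(rp[2]), 0, cos(rp[2])))
      R <- R %*% Ry %*% Rx
    }
    m <- diag(4); m[1:3, 1:3] <- R; m[1:3, 4] <- c(txy, tz)
    T_gt <- rigid_transform(m)
    source <- apply_transform(visible[[1]], rt_inverse(T_gt))
    target <- visible[[2]]
    ids <- lapply(visible, function(v) {
      tb <- table(v$branch_id[!is.na(v$branch_id)])
      as.integer(names(tb)[tb >= 20])
    })
    shared <- intersect(ids[[1]], ids[[2]])
    structure(list(source = source, target = target, T_gt = T_gt,
                   correspondence = cbind(src = shared, tgt = shared),
                   spec = attr(tree, "spec"),
                   stations = list(positions = stations, azimuths = azimuths,
                                   distance = distance, occlusion = occlusion)),
              class = "scan_pair")
  })
}

#' @export
print.scan_pair <- function(x, ...) {
  cat(sprintf("<scan_pair: source %d / target %d points, %d shared branches>\n",
              n_points(x$source), n_points(x$target), nrow(x$correspondence)))
  invisible(x)
}

#' Generate a suite of synthetic scan pairs
#'
#' `n` scan pairs with spec parameters redrawn per pair from the emulated
#' orchard ranges (8-18 branches, heights 2.5-3.7 m, basal trunk diameters
#' 5-8 cm), seeded `seed .. seed + n - 1` and bit-reproducible. When `dir`
#' is given, each pair is serialized (binary PLY scans + ground-truth
#' transform JSON) along with a `manifest.json`.
#'
#' @param n number of pairs.
#' @param base_spec a [tree_spec()] supplying every non-redrawn parameter.
#' @param seed base seed.
#' @param dir optional output directory.
#' @param ... forwarded to [simulate_two_stations()].
#' @return A list of `scan_pair` objects (invisibly when `dir` is given).
#' @export
make_fixture_suite <- function(n, base_spec = tree_spec(), seed = 0,
                               dir = NULL, ...) {
  stopifnot(n >= 1)
  pairs <- vector("list", n)
  manifest <- list()
  for (i in seq_len(n)) {
    si <- seed + i - 1L
    spec <- base_spec
    with_seed(si, {
      spec$n_branches <- sample(8:18, 1)
      spec$height <- runif(1, 2.5, 3.7)
      spec$basal_trunk_diameter <- runif(1, 0.05, 0.08)
    })
    spec$branch_insertion_height_range[2] <-
      min(spec$branch_insertion_height_range[2], spec$height - 0.3)
    spec$seed <- si
    tree <- generate_tree(spec)
    pair <- simulate_two_stations(tree, seed = si + 100003L, ...)
    pairs[[i]] <- pair
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      sf <- sprintf("pair%03d_source.ply", i)
      tf <- sprintf("pair%03d_target.ply", i)
      gf <- sprintf("pair%03d_gt.json", i)
      write_cloud(pair$source, file.path(dir, sf), binary = TRUE)
      write_cloud(pair$target, file.path(dir, tf), binary = TRUE)
      write_transform_json(pair$T_gt, file.path(dir, gf))
      manifest[[i]] <- list(source = sf, target = tf, gt = gf, seed = si,
                            n_branches = spec$n_branches,
                            T_gt = as.vector(t(unclass(pair$T_gt))))
    }
  }
  if (!is.null(dir)) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(pairs))
  }
  pairs
}
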