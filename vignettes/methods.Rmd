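---
title: "Registering opposed low-overlap laser scans of a single tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registering opposed low-overlap laser scans of a single tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treereg)
```

## The problem

Terrestrial laser scanning of individual orchard trees during dormancy
yields dense, millimeter-accurate point clouds, but a single station sees
only one side of the tree. Merging two stations placed on opposite sides
(180° apart) would complete the model — yet classical registration breaks
down there: the scans overlap only in a narrow silhouette band, so
descriptor matching (FPFH and relatives) and plain ICP either find no
correspondences or converge to a wrong pose. The usual workaround is
physical registration spheres placed in the scene, which costs field time.

`treereg` implements a marker-free alternative that exploits the
structural consistency of trees: the trunk and the primary branches are
observable from both viewpoints even when the *surfaces* barely overlap.
The pipeline matches one branch between the two scans by shape features
alone, derives a closed-form coarse alignment from it, and refines with a
trimmed, branch-only ICP.

## Pipeline

1. **Preprocessing** (`preprocess_cloud`). A ground plane is fitted by
   seeded RANSAC (3-point hypotheses, least-squares refit of the inlier
   set) and every height used downstream is a signed distance to this
   plane; the cloud is never re-leveled, because the coarse model assumes
   the scanner's vertical is shared between stations (4 degrees of
   freedom: yaw + translation). Ground points are removed (20 mm band),
   sparse noise is dropped by statistical outlier removal (k = 5 nearest
   neighbors, one-sided cut at the mean + 0.1 standard deviations of the
   per-point mean neighbor distances), and the cloud is thinned on an
   8 mm voxel grid (one centroid per occupied voxel).

2. **Branch matching** (`match_branches` and friends). In each scan the
   0.2–1.6 m height band is cut out — branches there are thick and
   wind-stable — and the trunk is fitted with a vertical-prior RANSAC
   cylinder. Points whose radial distance to the trunk axis lies in the
   0.07–0.14 m ring form short branch stubs: past the geometrically
   erratic branch–trunk junction, before secondary branching. Stubs are
   isolated by Euclidean clustering (12 mm tolerance, 40–2000 point
   gate), fitted with unconstrained RANSAC cylinders, and kept if at
   least 30% of the cluster lies on the fitted surface. Each surviving
   stub is summarized by three features: cylinder radius *r*, angle *θ*
   between branch and trunk axes (folded into [0, π/2]), and the height
   *h* of its point centroid. Candidate source–target pairings must pass
   all three tolerance gates (5 mm, 15°, 50 mm, strict); survivors get a
   fused residual with *dynamic weights*: each residual is normalized by
   its tolerance, weighted by its negative logarithm renormalized to sum
   to one, so the most consistent features dominate. One-to-one
   correspondence is enforced greedily in ascending score; among accepted
   pairs the one with the largest combined inlier count wins — fit
   quality as the final confidence measure. If no pairing passes the
   gates the registration *fails explicitly* rather than guessing.

3. **Coarse alignment** (`coarse_register`). The matched branch axes,
   oriented to point away from their trunks, are projected onto the
   horizontal plane; their intersection **O** is the rotation center and
   the signed angle between them the yaw α. T1 rotates about the vertical
   line through O (if the projections are near-parallel the source trunk
   footprint serves as center). Translation comes from the trunk: both
   scans' 0.20–0.30 m trunk slabs get vertical-prior cylinder fits, and
   T2 moves the source axis point at 0.25 m height onto the target's.
   Tc = T2·T1.

4. **Fine registration** (`fine_register`). Ground and trunk are excluded
   — they are geometrically simple, dominate the point count, and drag
   ICP into local minima — and a point-to-point ICP runs on the branch
   clouds only, keeping the closest 90% of correspondences each iteration
   (trimming) and discarding pairs beyond 40 mm. The final transform is
   T = Tf·Tc.

## Over-registration and its guard

On exactly opposed stations the two branch clouds are near-complementary
half-shells. Point-to-point ICP can then lower its own trimmed RMS by
*nesting* the shells — sliding roughly one branch radius along the
station axis — an over-registration: the residual improves while the pose
degrades. We bound this explicitly: if the refinement displaces any
branch point more than `drift_guard` (default 2 voxels = 16 mm) from its
coarse-aligned position, the translation is not trusted. The rotation
still is — the silhouette rim lines constrain it tightly, and in our
simulations the ICP rotation is an order of magnitude better than the
coarse one even when the translation has drifted. The recovery therefore
keeps the ICP rotation and re-anchors the translation with the same
basal-trunk-center construction the coarse stage uses; if even that
re-anchored pose sits farther than the guard from the coarse pose, the
coarse pose is returned unchanged. By construction the fine stage can
never move the pose more than the guard away from the coarse solution.

This bounded-drift construction is deliberately conservative: a large
*correct* rotation correction (a coarse yaw off by several degrees,
which a thin branch stub's axis can easily produce) also displaces
points beyond the guard and is then rejected, leaving that pair at
coarse accuracy. Pointwise error and matching success are insensitive
to this; the rotation and translation errors of individual pairs are
not. For scan pairs whose coarse alignment may be tens of millimeters
off (e.g. very noisy trunks), raise `drift_guard` accordingly.

## The synthetic scan simulator

`generate_tree` builds a labeled tall-spindle tree: a tapered vertical
trunk (default 3.3 m, 6.2 cm basal diameter, radius shrinking 25% per
meter), 8–18 straight branch frusta (1.4–3.3 cm basal diameter, inserted
at 0.3–2.8 m, 50–90° from the trunk axis, stratified azimuths), a ground
disc, ~2 mm surface sampling, and isotropic Gaussian sensor noise
(default 2 mm). Every point carries its semantic label, branch id and
analytic outward normal.

`simulate_two_stations` places two stations 2.3 m from the trunk at
opposed azimuths and keeps, per station, the points facing it. The
default `frontface` model retains points whose outward normal is within
5° past perpendicular to the viewing ray. This *grazing tolerance* is
what makes the two visible sets share a thin, nonzero silhouette band —
as real scans do, because beam footprint and surface roughness return
points slightly beyond 90° incidence; with a strict half-space split the
two scans would be exact complements with a measure-zero intersection,
which no physical scanner produces. The alternative `hpr` model is a
range-image visibility operator (angular depth buffer: nearest return
per 0.3° bin, 20 mm depth tolerance) for harder fixtures. Ground truth
is a sampled 4-DoF transform (yaw uniform, ±2 m horizontal, ±0.2 m
vertical; optional ≤0.5° roll/pitch via `pose_jitter`), applied inversely
to the source so that `T_gt` maps source to target.

What the simulator deliberately omits: secondary branches and twigs,
bark texture, branch curvature (off by default so feature oracles stay
closed-form; a flag enables it), inter-branch shadowing under
`frontface`, wind deformation, and foliage. Real winter scans contain
fine twig structure that gives ICP extra genuinely-shared geometry; the
simulator is therefore a *harder* case for the fine stage than reality,
and the over-registration guard earns its keep here. Passing the
synthetic suite demonstrates the pipeline's geometry end-to-end; it does
not certify performance on species or training systems whose key-region
geometry differs from the tall spindle.

## Parameter choices

Published tuning, kept as defaults: SOR k = 5 / multiplier 0.1; 8 mm
voxel; ring 0.07–0.14 m; inlier-ratio gate 30%; feature tolerances 5 mm /
15° / 50 mm; trunk slab 0.20–0.30 m (center read at 0.25 m); ICP overlap
ratio 90%; completeness threshold 5 mm.

Engineering defaults chosen here, with reasons:

* **Key height band 0.2–1.6 m** — above the basal slab used for
  translation, below the wind-prone crown.
* **Clustering tolerance 12 mm** — 1.5× the voxel size, so an 8 mm
  voxel-thinned surface (diagonal neighbors at 11.3 mm) stays connected.
* **Cluster size gate 40–2000 points** — a key-ring stub of a 1.4–3.3 cm
  branch spans ~8 cm of axis; its half-shell visible from one station
  carries only ~45–90 points after 8 mm voxeling, so the lower gate must
  sit below that while still discarding fragments.
* **Branch fit radius cap 5 cm** — primary apple branches never exceed a
  few cm; the cap also prevents near-planar clutter from being fitted as
  a giant-radius cylinder.
* **RANSAC controls** — trunk threshold 5 mm, branch threshold 4 mm,
  5000 iterations, normals from 10-NN PCA neighborhoods, axis prior ±10°
  for trunks only. Cylinder hypotheses come from two points plus their
  normals; the winner is refined twice by Levenberg–Marquardt on the
  orthogonal-distance residuals with the radius profiled out as the mean
  radial distance.
* **ICP stopping** — relative trimmed-RMS change below 1e-5 or 50
  iterations; a step that would increase the trimmed RMS is rolled back,
  making the RMS sequence non-increasing by construction.
* **Numerical edges** — arccos arguments clamped to [−1, 1]; normalized
  feature residuals clamped to [1e-6, 1−1e-6] with the analytic
  equal-residual limit w = 1/3, so the log-weights stay finite and
  `score(x,x,x) = x` holds exactly; threshold gates use strict
  inequality; signed 2D angles are counter-clockwise positive with the
  near-parallel case (|sin| < 1e-3) routed to a fallback rotation
  center.

Every default lives in `pipeline_config()` and can be overridden per
call or via the CLI's YAML config.

## Problem sizes used in the tests

The checked-in tests and the acceptance script sample synthetic surfaces
at 4–5 mm instead of the generator's 2 mm default. After the mandated
8 mm voxel filter the working geometry is identical — one point per
occupied voxel either way — while generation cost drops several-fold.
The end-to-end suite registers 20 seeded scan pairs at 2 mm noise with
8–18 branches; per-pair wall time is roughly 15 s on one core.

## Evaluation

`registration_report` follows the standard matrix-based and pointwise
conventions: rotation error is the axis-angle magnitude of the residual
rotation `arccos((tr(R̃Rᵀ)−1)/2)` in mrad; translation error the
Euclidean distance in mm; pointwise error the mean distance between
source points mapped by the estimated versus the true transform, with
per-axis means of absolute differences. A trial is a *success* when the
best-matching branch pair coincides with the ground-truth correspondence
(generator branch ids for synthetic scans). `completeness` reports the
fraction of a reference model covered within 5 mm by the test model; the
acceptance script computes it against a four-station reference built from
the same simulated surfaces, on the cleaned, unvoxelized models — two
independent voxelizations of the same surface would otherwise disagree by
up to half a voxel diagonal, swamping the 5 mm threshold with grid
artifacts. `structural_params` extracts tree height, basal trunk diameter
(0.20–0.30 m slab fit), and primary-branch counts and diameters (> 1 cm
basal diameter, measured in the same 0.07–0.14 m ring the matcher uses).

## Known limitations

* The 4-DoF coarse model requires leveled scanners; systematic roll or
  pitch between stations degrades it (the simulator's `pose_jitter`
  exercises small violations).
* One matched branch determines the yaw, so the coarse rotation accuracy
  is limited by how well an ~8 cm stub's axis can be estimated — a few
  mrad at 2 mm noise, worse for thin branches.
* Trees whose key region holds no gate-passing branch pair (too few
  branches, or several near-identical ones) fail explicitly; this
  mirrors the failure modes observed on real orchard data.
* The Euclidean-clustering ring segmentation assumes primary branches are
  radially separated; whorls of touching branches would merge into one
  cluster and likely fail the cylinder gate.
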