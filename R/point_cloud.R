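#' Point cloud container
#'
#' A thin S3 container for a 3D point cloud in meters: an `n x 3` coordinate
#' matrix plus optional per-point semantic labels (`ground`, `trunk`,
#' `branch`, `other`), ground-truth branch identifiers (synthetic scans only)
#' and analytic surface normals (used by the scan simulator's visibility
#' model).
#'
#' @param points numeric matrix with 3 columns (x, y, z) in meters.
#' @param labels optional character vector, one of `"ground"`, `"trunk"`,
#'   `"branch"`, `"other"` per point.
#' @param branch_id optional integer vector, one entry per point (`NA` for
#'   points that belong to no branch).
#' @param normals optional `n x 3` matrix of unit surface normals.
#' @return An object of class `point_cloud`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 0, 0)))
#' n_points(pc)
#' @export
point_cloud <- function(points, labels = NULL, branch_id = NULL, normals = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop_treereg("points must have 3 columns", "treereg_input_error")
  storage.mode(points) <- "double"
  if (nrow(points) > 0 && !all(is.finite(points)))
    stop_treereg("all coordinates must be finite", "treereg_input_error")
  dimnames(points) <- NULL
  n <- nrow(points)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n)
      stop_treereg("labels must have one entry per point", "treereg_input_error")
    bad <- setdiff(unique(labels), c("ground", "trunk", "branch", "other"))
    if (length(bad))
      stop_treereg(paste0("unknown label(s): ", paste(bad, collapse = ", ")),
                   "treereg_input_error")
  }
  if (!is.null(branch_id)) {
    branch_id <- as.integer(branch_id)
    if (length(branch_id) != n)
      stop_treereg("branch_id must have one entry per point", "treereg_input_error")
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == c(n, 3)))
      stop_treereg("normals must be an n x 3 matrix", "treereg_input_error")
  }
  structure(list(points = points, labels = labels, branch_id = branch_id,
                 normals = normals),
            class = "point_cloud")
}

#' Number of points in a cloud
#' @param cloud a [point_cloud()].
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a point cloud by index
#'
#' Keeps per-point attributes (labels, branch ids, normals) in step with the
#' coordinates.
#'
#' @param cloud a [point_cloud()].
#' @param idx integer or logical index vector.
#' @return A [point_cloud()] with the selected points, in index order.
#' @export
subset_cloud <- function(cloud, idx) {
  point_cloud(cloud$points[idx, , drop = FALSE],
              labels = if (!is.null(cloud$labels)) cloud$labels[idx],
              branch_id = if (!is.null(cloud$branch_id)) cloud$branch_id[idx],
              normals = if (!is.null(cloud$normals)) cloud$normals[idx, , drop = FALSE])
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud: %d points%s%s%s>\n", n_points(x),
              if (!is.null(x$labels)) ", labeled" else "",
              if (!is.null(x$branch_id)) ", branch ids" else "",
              if (!is.null(x$normals)) ", normals" else ""))
  invisible(x)
}
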