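# Rigid transforms as 4x4 homogeneous matrices mapping source coordinates
# into the target frame. The coarse stage is 4-DoF (yaw + translation),
# matching the leveled-scanner assumption; composition is plain matrix
# multiplication applied right-to-left.

#' Construct a rigid transform
#'
#' Validates a 4x4 homogeneous matrix: bottom row `(0,0,0,1)` and an
#' orthonormal rotation block with determinant +1.
#'
#' @param matrix a 4x4 numeric matrix.
#' @param tol validation tolerance.
#' @return An object of class `rigid_transform` (a 4x4 matrix).
#' @export
rigid_transform <- function(matrix, tol = 1e-9) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(4, 4)))
    stop_treereg("a rigid transform is a 4x4 matrix", "treereg_input_error")
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > tol)
    stop_treereg("bottom row must be (0, 0, 0, 1)", "treereg_input_error")
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > sqrt(tol) || det(R) < 0)
    stop_treereg("rotation block must be orthonormal with determinant +1",
                 "treereg_input_error")
  structure(matrix, class = c("rigid_transform", "matrix", "array"))
}

#' Identity transform
#' @return A [rigid_transform()].
#' @export
rt_identity <- function() rigid_transform(diag(4))

#' Yaw rotation about a vertical line
#'
#' Rotation by `alpha` (counter-clockwise, radians) about the vertical axis
#' through the planar point `O = (x_o, y_o)`: the composition
#' shift-to-origin, rotate about z, shift back, whose closed form has
#' translation part `(x_o (1 - cos a) + y_o sin a, y_o (1 - cos a) - x_o sin a, 0)`.
#'
#' @param alpha rotation angle in radians.
#' @param O length-2 rotation center in the XOY plane.
#' @return A [rigid_transform()] that fixes the vertical line through `O`.
#' @export
rt_rot_z_about <- function(alpha, O = c(0, 0)) {
  ca <- cos(alpha); sa <- sin(alpha)
  m <- diag(4)
  m[1, 1] <- ca; m[1, 2] <- -sa
  m[2, 1] <- sa; m[2, 2] <- ca
  m[1, 4] <- O[1] * (1 - ca) + O[2] * sa
  m[2, 4] <- O[2] * (1 - ca) - O[1] * sa
  rigid_transform(m)
}

#' Pure translation transform
#' @param t length-3 translation vector (m).
#' @return A [rigid_transform()].
#' @export
rt_translation <- function(t) {
  m <- diag(4)
  m[1:3, 4] <- t
  rigid_transform(m)
}

#' Rotation block and translation vector of a transform
#' @param T a [rigid_transform()] (or plain 4x4 matrix).
#' @return `rotation_block`: 3x3 matrix; `translation_vec`: length-3 vector.
#' @export
rotation_block <- function(T) unclass(T)[1:3, 1:3, drop = TRUE]

#' @rdname rotation_block
#' @export
translation_vec <- function(T) unclass(T)[1:3, 4]

#' Invert a rigid transform
#' @param T a [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
rt_inverse <- function(T) {
  R <- rotation_block(T)
  t <- translation_vec(T)
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t
  rigid_transform(m)
}

#' Apply a rigid transform to a point cloud
#'
#' Every point is mapped by the homogeneous product; labels and branch ids
#' are carried through and normals are rotated.
#'
#' @param cloud a [point_cloud()].
#' @param T a [rigid_transform()].
#' @return The transformed [point_cloud()].
#' @export
apply_transform <- function(cloud, T) {
  P <- transform_points(cloud$points, T)
  N <- if (!is.null(cloud$normals)) cloud$normals %*% t(rotation_block(T))
  point_cloud(P, labels = cloud$labels, branch_id = cloud$branch_id, normals = N)
}

#' @rdname apply_transform
#' @param points an `n x 3` coordinate matrix.
#' @export
transform_points <- function(points, T) {
  R <- rotation_block(T)
  t <- translation_vec(T)
  sweep(points %*% t(R), 2, t, `+`)
}

# plane transforms with the inverse-transpose rule; for rigid maps that is
# (R n, offset - (R n) . t)
transform_plane <- function(plane, T) {
  R <- rotation_block(T)
  t <- translation_vec(T)
  n <- as.vector(R %*% plane$normal)
  ground_plane(normal = n, offset = plane$offset - sum(n * t),
               inlier_count = plane$inlier_count)
}

#' Read and write transforms
#'
#' JSON carries the full registration record (matrix row-major plus coarse
#' diagnostics when available); the plain-text format is 4 rows of 4
#' whitespace-separated numbers for interoperability.
#'
#' @param T a [rigid_transform()].
#' @param path file path.
#' @param extra optional named list merged into the JSON record (e.g.
#'   `alpha_rad`, `O`, `G_src`, `G_tgt`, `icp`).
#' @return Readers return a [rigid_transform()]; for JSON the remaining
#'   fields are attached as attribute `"meta"`.
#' @export
write_transform_json <- function(T, path, extra = list()) {
  rec <- c(list(matrix = as.vector(t(unclass(T)))), extra)
  # 17 significant digits: doubles round-trip bit-exactly through the file
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rec$matrix) || length(rec$matrix) != 16)
    stop_treereg(paste0("malformed transform JSON: ", path), "treereg_parse_error")
  T <- rigid_transform(matrix(as.numeric(rec$matrix), 4, 4, byrow = TRUE))
  attr(T, "meta") <- rec[setdiff(names(rec), "matrix")]
  T
}

#' @rdname write_transform_json
#' @export
write_transform_matrix <- function(T, path) {
  writeLines(apply(unclass(T), 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             path)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_matrix <- function(path) {
  v <- scan(path, quiet = TRUE)
  if (length(v) != 16)
    stop_treereg(paste0("transform matrix file must hold 16 numbers: ", path),
                 "treereg_parse_error")
  rigid_transform(matrix(v, 4, 4, byrow = TRUE))
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(unclass(x))
  invisible(x)
}
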