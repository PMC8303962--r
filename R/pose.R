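#' @useDynLib orthoreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd
NULL

DEG <- pi / 180

#' Six-degree-of-freedom rigid pose
#'
#' A rigid-body pose parameterized as three rotation angles about the fixed
#' x, y and z axes plus a translation. Angles are stored in radians; every
#' user-facing boundary (CLI, config files, manifests, printed errors) uses
#' degrees. The rotation matrix is composed extrinsically as
#' `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)`.
#'
#' @param alpha,beta,gamma rotation angles about x, y, z (radians).
#' @param tx,ty,tz translations along x, y, z (mm).
#' @return An object of class `pose6`, a named numeric vector of length 6.
#' @examples
#' pose6()                      # identity
#' pose_from_degrees(5, -3, 8, 4, -7, 2)
#' @export
pose6 <- function(alpha = 0, beta = 0, gamma = 0, tx = 0, ty = 0, tz = 0) {
  p <- c(alpha = alpha, beta = beta, gamma = gamma, tx = tx, ty = ty, tz = tz)
  if (!is.numeric(p) || length(p) != 6L || any(!is.finite(p)))
    stop("pose parameters must be six finite numbers")
  structure(p, class = "pose6")
}

#' @rdname pose6
#' @param alpha_deg,beta_deg,gamma_deg rotation angles in degrees.
#' @export
pose_from_degrees <- function(alpha_deg = 0, beta_deg = 0, gamma_deg = 0,
                              tx = 0, ty = 0, tz = 0) {
  pose6(alpha_deg * DEG, beta_deg * DEG, gamma_deg * DEG, tx, ty, tz)
}

#' @export
print.pose6 <- function(x, ...) {
  cat(sprintf(
    "pose6: rot (%.4f, %.4f, %.4f) deg  trans (%.4f, %.4f, %.4f) mm\n",
    x[1] / DEG, x[2] / DEG, x[3] / DEG, x[4], x[5], x[6]))
  invisible(x)
}

as_pose6 <- function(p) {
  if (inherits(p, "pose6")) return(p)
  if (is.numeric(p) && length(p) == 6L) return(pose6(p[1], p[2], p[3], p[4], p[5], p[6]))
  stop("cannot interpret input as a 6-DoF pose")
}

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

# derivative of each elementary rotation with respect to its angle
drot_x <- function(a) matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
drot_y <- function(a) matrix(c(-sin(a), 0, -cos(a), 0, 0, 0, cos(a), 0, -sin(a)), 3, 3)
drot_z <- function(a) matrix(c(-sin(a), cos(a), 0, -cos(a), -sin(a), 0, 0, 0, 0), 3, 3)

rotation_matrix <- function(pose) {
  pose <- as_pose6(pose)
  rot_z(pose[3]) %*% rot_y(pose[2]) %*% rot_x(pose[1])
}

#' Rigid transform as a homogeneous 4x4 matrix
#'
#' @param matrix a 4x4 homogeneous matrix with orthonormal rotation block,
#'   unit determinant and bottom row (0, 0, 0, 1).
#' @param center rotation center (mm) recorded at construction; metadata only.
#' @param tol orthonormality tolerance for validation.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(matrix = diag(4), center = c(0, 0, 0), tol = 1e-6) {
  m <- base::matrix(as.numeric(matrix), 4, 4)
  if (any(!is.finite(m))) stop("transform matrix must be finite")
  R <- m[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("matrix is not a rigid transform (orthonormality/determinant violated)")
  m[4, ] <- c(0, 0, 0, 1)
  structure(list(matrix = m, center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform (center", paste(signif(x$center, 6), collapse = ", "), "mm)\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Convert a pose to its homogeneous-matrix form
#'
#' Builds the 4x4 matrix that rotates about `center` by
#' `Rz(gamma) %*% Ry(beta) %*% Rx(alpha)` and then translates:
#' `p -> R (p - c) + c + t`.
#'
#' @param pose a [pose6()].
#' @param center rotation center (mm). Registration routines default this to
#'   the moving volume's world-space center.
#' @return A [rigid_transform()].
#' @export
pose_to_matrix <- function(pose, center = c(0, 0, 0)) {
  pose <- as_pose6(pose)
  center <- as.numeric(center)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("center must be a finite 3-vector")
  R <- rotation_matrix(pose)
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- center + pose[4:6] - R %*% center
  rigid_transform(m, center = center)
}

#' Recover the 6-DoF pose from a rigid transform
#'
#' Inverts [pose_to_matrix()] under the same extrinsic x-y-z Euler
#' convention. At gimbal lock (`|beta| = pi/2`) the decomposition is not
#' unique; the `gamma = 0` branch is taken and the residual in-plane rotation
#' folded into `alpha`, so the returned pose always re-synthesizes the input
#' matrix.
#'
#' @param transform a [rigid_transform()].
#' @param center rotation center (mm); defaults to the center stored in
#'   `transform`.
#' @return A [pose6()].
#' @export
matrix_to_pose <- function(transform, center = NULL) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.null(center)) center <- transform$center
  center <- as.numeric(center)
  m <- transform$matrix
  R <- m[1:3, 1:3]
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  beta <- asin(sb)
  if (abs(abs(sb) - 1) < 1e-12) {
    # gimbal lock: cos(beta) = 0, only alpha -+ gamma is determined; pick gamma = 0
    gamma <- 0
    if (sb > 0) {                        # beta = +pi/2: R[1,2] = sin(a-g)... with g=0
      alpha <- atan2(R[1, 2], R[1, 3])
    } else {                             # beta = -pi/2
      alpha <- atan2(-R[1, 2], -R[1, 3])
    }
  } else {
    alpha <- atan2(R[3, 2], R[3, 3])
    gamma <- atan2(R[2, 1], R[1, 1])
  }
  t <- m[1:3, 4] - center + R %*% center
  pose6(alpha, beta, gamma, t[1], t[2], t[3])
}

#' Compose, invert and apply rigid transforms
#'
#' `compose(A, B)` returns the transform applying `B` first, then `A`
#' (matrix product `A %*% B`). `invert_transform` returns the group inverse.
#' `apply_points` maps world points through a transform.
#'
#' @param A,B,transform [rigid_transform()] objects.
#' @param points an n-by-3 matrix of world coordinates (mm), or a 3-vector.
#' @return A transform, or mapped points with the input's shape.
#' @export
compose <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  rigid_transform(A$matrix %*% B$matrix, center = A$center)
}

#' @rdname compose
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- transform$matrix
  R <- t(m[1:3, 1:3])
  inv <- diag(4)
  inv[1:3, 1:3] <- R
  inv[1:3, 4] <- -R %*% m[1:3, 4]
  rigid_transform(inv, center = transform$center)
}

#' @rdname compose
#' @export
apply_points <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  pts <- if (vec) base::matrix(as.numeric(points), 1, 3) else as.matrix(points)
  if (ncol(pts) != 3L) stop("points must be n x 3")
  out <- pts %*% t(transform$matrix[1:3, 1:3])
  out <- sweep(out, 2, transform$matrix[1:3, 4], "+")
  if (vec) drop(out) else out
}

#' Fixed transform between the AP view and a second view
#'
#' Rotation about the cranio-caudal (z) axis mapping the anterior-posterior
#' view frame into the second (lateral at 90 degrees) view frame. The view
#' angle is the angle between the two X-ray directions.
#'
#' @param angle_deg inter-view angle in degrees, in (0, 180).
#' @param center rotation center (mm), normally the imaging isocenter.
#' @return A [rigid_transform()].
#' @export
lat_view_transform <- function(angle_deg = 90, center = c(0, 0, 0)) {
  if (!is.finite(angle_deg) || angle_deg <= 0 || angle_deg >= 180)
    stop("view angle must lie strictly between 0 and 180 degrees")
  pose_to_matrix(pose6(gamma = angle_deg * DEG), center = center)
}

#' Read and write pose JSON
#'
#' Poses are serialized in degrees/mm with the Euler convention and rotation
#' center recorded, so ground-truth poses are unambiguous across tools.
#'
#' @param pose a [pose6()].
#' @param path file path.
#' @param center_mm rotation center stored alongside the pose.
#' @return `read_pose_json` returns a list with elements `pose` and `center`.
#' @export
write_pose_json <- function(pose, path, center_mm = c(0, 0, 0)) {
  pose <- as_pose6(pose)
  obj <- list(
    alpha_deg = pose[[1]] / DEG, beta_deg = pose[[2]] / DEG,
    gamma_deg = pose[[3]] / DEG,
    tx_mm = pose[[4]], ty_mm = pose[[5]], tz_mm = pose[[6]],
    euler_convention = "extrinsic x-y-z (R = Rz * Ry * Rx)",
    center_mm = as.numeric(center_mm))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pose_json
#' @export
read_pose_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(pose = pose_from_degrees(obj$alpha_deg, obj$beta_deg, obj$gamma_deg,
                                obj$tx_mm, obj$ty_mm, obj$tz_mm),
       center = as.numeric(obj$center_mm))
}
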