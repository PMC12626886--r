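#' Rigid-body pose
#'
#' A pose is a proper rigid transform: a 3x3 rotation matrix (orthonormal,
#' determinant +1) plus a translation in Angstrom. Poses are attached to
#' particles, ring spokes and rigid bodies throughout the package. The
#' stored matrix is authoritative; ZYZ Euler angles are a derived view
#' ([pose_angles()]) kept only for human-readable tables.
#'
#' @param rotation 3x3 rotation matrix.
#' @param shift numeric translation vector, Angstrom.
#' @return An object of class `"pose"` with elements `rotation` and `shift`.
#' @examples
#' p <- pose(rot_z(45), c(10, 0, 0))
#' pose_angles(p)
#' @export
pose <- function(rotation = diag(3), shift = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  shift <- as.numeric(shift)
  stopifnot(all(dim(rotation) == c(3, 3)), length(shift) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("pose(): rotation matrix is not orthonormal")
  }
  if (abs(det(rotation) - 1) > 1e-6) {
    stop("pose(): rotation matrix must have determinant +1")
  }
  structure(list(rotation = rotation, shift = shift), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  ang <- pose_angles(x)
  cat(sprintf("<pose> ZYZ = (%.2f, %.2f, %.2f) deg, shift = (%.2f, %.2f, %.2f) A\n",
              ang[1], ang[2], ang[3], x$shift[1], x$shift[2], x$shift[3]))
  invisible(x)
}

#' Elementary and Euler rotation matrices
#'
#' `rot_x`, `rot_y`, `rot_z` build rotations about the coordinate axes;
#' `rot_zyz` composes the intrinsic Z-Y-Z convention used for all angular
#' grids and pose tables: `R = Rz(phi) %*% Ry(theta) %*% Rz(psi)`. All
#' angles are degrees, right-handed.
#'
#' @param angle,phi,theta,psi rotation angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_z <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @export
rot_y <- function(angle) {
  a <- angle * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_x <- function(angle) {
  a <- angle * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rot_z
#' @export
rot_zyz <- function(phi, theta, psi) {
  rot_z(phi) %*% rot_y(theta) %*% rot_z(psi)
}

#' Recover ZYZ Euler angles from a pose or rotation matrix
#'
#' @param x a `pose` or a 3x3 rotation matrix.
#' @return Numeric vector `c(phi, theta, psi)` in degrees.
#' @export
pose_angles <- function(x) {
  R <- if (inherits(x, "pose")) x$rotation else as.matrix(x)
  theta <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(theta)) < 1e-9) {
    # Gimbal lock: fold everything into phi.
    phi <- atan2(R[2, 1], R[1, 1])
    psi <- 0
    if (R[3, 3] < 0) theta <- pi
  } else {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  }
  c(phi = phi, theta = theta, psi = psi) * 180 / pi
}

#' Angle of the residual rotation between two rotations
#'
#' The geodesic distance on SO(3): the rotation angle of `A %*% t(B)`,
#' used to measure how far an estimated pose is from ground truth.
#'
#' @param A,B rotation matrices or poses.
#' @return Angle in degrees, in `[0, 180]`.
#' @export
rotation_distance <- function(A, B = diag(3)) {
  if (inherits(A, "pose")) A <- A$rotation
  if (inherits(B, "pose")) B <- B$rotation
  tr <- sum(diag(A %*% t(B)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

# Compose two poses: (p2 o p1)(x) = R2 (R1 x + t1) + t2
compose_pose <- function(p2, p1) {
  pose(p2$rotation %*% p1$rotation,
       as.numeric(p2$rotation %*% p1$shift) + p2$shift)
}

invert_pose <- function(p) {
  pose(t(p$rotation), -as.numeric(t(p$rotation) %*% p$shift))
}

# Uniformly random rotation matrix (uses current RNG stream).
random_rotation <- function() {
  # Shoemake quaternion method
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + z * w), 2 * (x * z - y * w),
    2 * (x * y - z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z + x * w),
    2 * (x * z + y * w), 2 * (y * z - x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3)
}

# Small random rotation with angle <= max_angle degrees about a random axis.
random_small_rotation <- function(max_angle) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  axis_angle_matrix(ax, runif(1, 0, max_angle))
}

#' Rotation matrix from axis and angle
#'
#' @param axis rotation axis (any nonzero length).
#' @param angle_deg rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}
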