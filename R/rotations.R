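# Rotation helpers shared by the model, kinematics and synthetic-rig modules.
# Hip orientation uses the intrinsic Z-X-Y Euler sequence (flexion about the
# vertical axis is not meaningful here; the sequence is a modeling convention).

skew3 <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

rot_axis <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  S <- skew3(a)
  diag(3) + sin(theta) * S + (1 - cos(theta)) * (S %*% S)
}

rot_x <- function(t) rot_axis(c(1, 0, 0), t)
rot_y <- function(t) rot_axis(c(0, 1, 0), t)
rot_z <- function(t) rot_axis(c(0, 0, 1), t)

#' Euler Z-X-Y rotation matrix
#'
#' Composes `Rz(a1) %*% Rx(a2) %*% Ry(a3)`, the intrinsic sequence used for
#' the three driven hip angles.
#'
#' @param angles numeric length-3, radians.
#' @return 3x3 rotation matrix.
#' @export
euler_zxy <- function(angles) {
  rot_z(angles[1]) %*% rot_x(angles[2]) %*% rot_y(angles[3])
}

#' Extract Z-X-Y Euler angles from a rotation matrix
#'
#' Inverse of [euler_zxy()]. The middle (X) angle is returned in
#' `[-pi/2, pi/2]`; proximity to the gimbal singularity can be detected by
#' comparing `abs(angles[2])` against `pi/2`.
#'
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 angles (radians).
#' @export
euler_zxy_inverse <- function(R) {
  s2 <- max(-1, min(1, R[3, 2]))
  a2 <- asin(s2)
  a3 <- atan2(-R[3, 1], R[3, 3])
  a1 <- atan2(-R[1, 2], R[2, 2])
  c(a1, a2, a3)
}

# signed rotation angle of R about a fixed unit axis (R must be a rotation
# about that axis for the result to be exact)
axis_angle_about <- function(R, axis) {
  a <- axis / sqrt(sum(axis^2))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  atan2(sum(ax * a), (sum(diag(R)) - 1) / 2)
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) <= tol && det(R) > 0
}
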