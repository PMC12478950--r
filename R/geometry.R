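# Rotation and frame utilities shared by the mirroring and kinematics code.
# Convention throughout: column vectors, body-fixed X-Y-Z Euler angles,
# R = Rx(a) %*% Ry(b) %*% Rz(c), radians.

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Body-fixed XYZ Euler angles to a rotation matrix
#'
#' @param e numeric length-3 vector of rotations about x, y, z (rad),
#'   composed body-fixed: `R = Rx(e1) Ry(e2) Rz(e3)`.
#' @return 3x3 rotation matrix.
#' @keywords internal
euler_xyz_to_matrix <- function(e) {
  stopifnot(length(e) == 3, all(is.finite(e)))
  rot_x(e[1]) %*% rot_y(e[2]) %*% rot_z(e[3])
}

#' Rotation matrix to body-fixed XYZ Euler angles
#'
#' Inverse of [euler_xyz_to_matrix()]. At the gimbal singularity
#' (|second angle| = pi/2 within 1e-9) the third angle is set to 0 and the
#' whole in-plane rotation is folded into the first angle, giving a
#' deterministic round-trip.
#'
#' @param R 3x3 proper rotation matrix.
#' @return numeric length-3 Euler vector (rad).
#' @keywords internal
matrix_to_euler_xyz <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  # R[1,3] = sin(b) for R = Rx(a) Ry(b) Rz(c)
  sb <- max(-1, min(1, R[1, 3]))
  if (abs(abs(sb) - 1) < 1e-9) {
    b <- asin(sb)
    # gimbal branch: c := 0, fold into a; R reduces so that
    # R[2,1] = sin(a +/- c)-type combination; recover a from the 2x2 block
    a <- atan2(R[2, 1], R[2, 2])
    c <- 0
  } else {
    b <- asin(sb)
    a <- atan2(-R[2, 3], R[3, 3])
    c <- atan2(-R[1, 2], R[1, 1])
  }
  c(a, b, c)
}

#' Axis-angle rotation matrix (Rodrigues)
#' @param axis unit 3-vector.
#' @param theta angle (rad).
#' @keywords internal
rot_axis_angle <- function(axis, theta) {
  n <- axis / sqrt(sum(axis^2))
  ct <- cos(theta); st <- sin(theta)
  K <- matrix(c(0, n[3], -n[2], -n[3], 0, n[1], n[2], -n[1], 0), 3, 3)
  diag(3) * ct + st * K + (1 - ct) * (n %o% n)
}

# homogeneous 4x4 from rotation + translation
hom_transform <- function(R = diag(3), p = c(0, 0, 0)) {
  X <- diag(4)
  X[1:3, 1:3] <- R
  X[1:3, 4] <- p
  X
}

# apply 4x4 to a 3-point (or 3xN matrix of column points)
transform_point <- function(X, p) {
  if (is.matrix(p)) {
    X[1:3, 1:3] %*% p + X[1:3, 4]
  } else {
    drop(X[1:3, 1:3] %*% p) + X[1:3, 4]
  }
}

# extract the rotation-vector of a small rotation dR ~ I + [w]x
small_rotation_vector <- function(dR) {
  c(dR[3, 2] - dR[2, 3], dR[1, 3] - dR[3, 1], dR[2, 1] - dR[1, 2]) / 2
}

# inertia vector (ixx,iyy,izz,ixy,ixz,iyz) <-> symmetric 3x3
inertia_to_matrix <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

matrix_to_inertia <- function(M) {
  c(M[1, 1], M[2, 2], M[3, 3], M[1, 2], M[1, 3], M[2, 3])
}
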