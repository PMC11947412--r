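# Internal rigid-body geometry helpers. All rotation matrices are 3x3 proper
# orthogonal; vectors are plain numeric length-3. Angles in radians here;
# user-facing functions convert at the boundary.

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0,
           0, c, s,
           0, -s, c), 3, 3)
}

rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, -s,
           0, 1, 0,
           s, 0, c), 3, 3)
}

rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, s, 0,
           -s, c, 0,
           0, 0, 1), 3, 3)
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation matrix about a (non-zero) axis by an angle.
#'
#' @param axis numeric(3), need not be unit length.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper orthogonal matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) stop("rotation axis must be non-zero")
  u <- axis / n
  a <- angle_deg * DEG2RAD
  K <- skew3(u)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v^2))

is_proper_rotation <- function(R, tol = 1e-10) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(R %*% t(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

# axis-angle decomposition; returns list(axis, angle_deg), angle in [0, 180]
axis_angle <- function(R) {
  ca <- (sum(diag(R)) - 1) / 2
  ca <- min(1, max(-1, ca))
  a <- acos(ca)
  if (a < 1e-12) return(list(axis = c(1, 0, 0), angle_deg = 0))
  if (abs(pi - a) < 1e-8) {
    # near 180 deg: axis from the symmetric part
    B <- (R + diag(3)) / 2
    u <- sqrt(pmax(diag(B), 0))
    # fix signs from off-diagonals
    i <- which.max(u)
    if (i == 1L) u <- c(u[1], B[1, 2] / u[1], B[1, 3] / u[1])
    if (i == 2L) u <- c(B[1, 2] / u[2], u[2], B[2, 3] / u[2])
    if (i == 3L) u <- c(B[1, 3] / u[3], B[2, 3] / u[3], u[3])
    return(list(axis = u / norm3(u), angle_deg = a * RAD2DEG))
  }
  u <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(a))
  list(axis = u, angle_deg = a * RAD2DEG)
}
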