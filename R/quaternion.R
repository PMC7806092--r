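#' Quaternion and vector kinematics primitives
#'
#' Unit quaternions are stored as plain numeric vectors of length 4 in
#' scalar-first order `(w, x, y, z)`, Hamilton convention: a rotation acts on
#' a 3-vector `v` as `q %q% v %q% q*` with `v` treated as a pure quaternion.
#' All frames are right-handed with the z-axis pointing straight up.
#' Angles at the user interface are in degrees; internal trigonometry is in
#' radians.
#'
#' @name quaternion
NULL

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

#' Construct a quaternion
#'
#' @param w,x,y,z Scalar components, scalar first.
#' @return Numeric vector `c(w, x, y, z)`.
#' @export
quat <- function(w, x, y, z) c(w, x, y, z)

#' Identity quaternion
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Hamilton product of two quaternions
#'
#' @param a,b Quaternions as length-4 numerics, scalar first.
#' @return The product `a %*% b` (Hamilton convention).
#' @export
quat_multiply <- function(a, b) {
  a <- unname(a); b <- unname(b)
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#' @param q Quaternion.
#' @export
quat_conjugate <- function(q) { q <- unname(q); c(q[1], -q[2], -q[3], -q[4]) }

#' Normalize a quaternion to unit norm
#' @param q Quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes `q \%q\% v \%q\% q*`, i.e. expresses a body-frame vector in the
#' parent frame of `q`.
#'
#' @param q Unit quaternion.
#' @param v Numeric 3-vector.
#' @param tol Tolerance on `|norm(q) - 1|` before the call is rejected.
#' @return Rotated 3-vector.
#' @export
quat_rotate <- function(q, v, tol = 1e-6) {
  if (abs(sum(q^2) - 1) > tol) stop("quat_rotate: q is not a unit quaternion")
  q <- unname(q); v <- unname(v)
  w <- q[1]; u <- q[2:4]
  # Rodrigues-style expansion of q (0,v) q*
  v + 2 * w * cross3(u, v) + 2 * cross3(u, cross3(u, v))
}

# Row-wise rotation: Q is n x 4, V is n x 3; returns n x 3.
quat_rotate_rows <- function(Q, V) {
  w <- Q[, 1]; ux <- Q[, 2]; uy <- Q[, 3]; uz <- Q[, 4]
  vx <- V[, 1]; vy <- V[, 2]; vz <- V[, 3]
  cx <- uy * vz - uz * vy
  cy <- uz * vx - ux * vz
  cz <- ux * vy - uy * vx
  # u x (u x v)
  dx <- uy * cz - uz * cy
  dy <- uz * cx - ux * cz
  dz <- ux * cy - uy * cx
  cbind(vx + 2 * (w * cx + dx),
        vy + 2 * (w * cy + dy),
        vz + 2 * (w * cz + dz))
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix `R` with `R v = quat_rotate(q, v)`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Quaternion from axis and angle
#' @param axis Rotation axis (need not be unit).
#' @param angle_rad Rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle_rad) {
  n <- sqrt(sum(axis^2))
  if (n == 0) return(quat_identity())
  u <- axis / n
  c(cos(angle_rad / 2), sin(angle_rad / 2) * u)
}

#' Heading (yaw) quaternion about the vertical axis
#'
#' Rotation about the z-axis by `delta_deg` degrees,
#' `(cos(d/2), 0, 0, sin(d/2))`.
#'
#' @param delta_deg Heading angle in degrees.
#' @export
heading_quat <- function(delta_deg) {
  h <- deg2rad(delta_deg) / 2
  c(cos(h), 0, 0, sin(h))
}

#' Heading angle of an orientation
#'
#' The azimuth, in degrees, of the rotated body x-axis projected onto the
#' horizontal plane. Undefined (NA) when the x-axis is vertical.
#'
#' @param q Unit quaternion.
#' @export
quat_heading <- function(q) {
  v <- quat_rotate(q, c(1, 0, 0))
  if (sqrt(v[1]^2 + v[2]^2) < 1e-9) return(NA_real_)
  rad2deg(atan2(v[2], v[1]))
}

#' Cross-product matrix
#'
#' Skew-symmetric matrix `[v]_x` such that `[v]_x %*% b == v x b`.
#'
#' @param v Numeric 3-vector.
#' @export
cross_matrix <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), nrow = 3, byrow = TRUE)
}

#' Cross product of two 3-vectors
#' @param a,b Numeric 3-vectors.
#' @export
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Normalize a vector to unit Euclidean norm
#' @param v Numeric vector with positive norm.
#' @export
normalize_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("normalize_vec: zero vector (degenerate geometry)")
  v / n
}

#' Wrap an angle into (-180, 180] degrees
#' @param a_deg Angle(s) in degrees.
#' @export
wrap_angle <- function(a_deg) {
  w <- a_deg - 360 * floor(a_deg / 360)  # [0, 360)
  ifelse(w > 180, w - 360, w)
}

#' Wrap an angle into [0, 360) degrees
#' @param a_deg Angle(s) in degrees.
#' @export
wrap_360 <- function(a_deg) a_deg - 360 * floor(a_deg / 360)
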