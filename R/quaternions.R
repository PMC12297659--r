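# Unit-quaternion utilities (scalar-first convention: q = (w, x, y, z)).
# Rotations act on column points as R(q) %*% x.

#' Quaternion from an axis and angle
#' @param axis length-3 axis (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @return length-4 unit quaternion (w, x, y, z).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-300) return(c(1, 0, 0, 0))
  a <- angle_deg * pi / 360
  c(cos(a), sin(a) * axis / n)
}

#' Quaternion product
#' @param a,b length-4 quaternions; the product rotates by `b` first, then `a`.
#' @return length-4 quaternion.
#' @export
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Rotation matrix of a unit quaternion
#' @param q length-4 unit quaternion.
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

#' Rotate points by a quaternion
#' @param q length-4 unit quaternion.
#' @param xyz n x 3 matrix of points (rows).
#' @return n x 3 matrix of rotated points.
#' @export
quat_rotate <- function(q, xyz) xyz %*% t(quat_to_matrix(q))

#' Geodesic angle between two rotations
#' @param a,b length-4 unit quaternions.
#' @return relative rotation angle in degrees, in \[0, 180\].
#' @export
quat_angle_deg <- function(a, b = c(1, 0, 0, 0)) {
  d <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  2 * acos(min(1, d)) * 180 / pi
}

# Uniform random unit quaternion from the current RNG stream.
quat_random <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}
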