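#' Unit quaternion construction
#'
#' Quaternions here follow the Hamilton convention and represent rotations of
#' the world frame from the body frame (`q` rotates body-frame vectors into
#' the world frame). The world frame is gravity-aligned with +Y up.
#'
#' @param w,x,y,z Numeric scalar components.
#' @param normalize If `TRUE` (default) the quaternion is renormalised to unit
#'   norm; a zero-norm quaternion is an error.
#' @return A numeric vector of length 4, class `"quaternion"`, components
#'   named `w, x, y, z`.
#' @examples
#' quat(1, 0, 0, 0)                       # identity
#' quat_from_axis_angle(c(0, 1, 0), pi/2) # 90 degrees about Y
#' @export
quat <- function(w, x, y, z, normalize = TRUE) {
  q <- c(w = w, x = x, y = y, z = z)
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  if (normalize) {
    n <- sqrt(sum(q^2))
    if (n < 1e-12) stop("cannot normalize a zero quaternion")
    q <- q / n
  }
  class(q) <- "quaternion"
  q
}

#' @rdname quat
#' @export
quat_identity <- function() quat(1, 0, 0, 0, normalize = FALSE)

quat_norm <- function(q) sqrt(sum(unclass(q)^2))

stopifnot_unit_quat <- function(q, tol = 1e-6) {
  if (length(q) != 4L || !all(is.finite(q)))
    stop("expected a quaternion (4 finite components)")
  if (abs(quat_norm(q) - 1) > tol)
    stop("expected a unit quaternion (|q| = 1 within ", tol, ")")
  invisible(q)
}

#' Quaternion conjugate (inverse rotation for unit quaternions)
#'
#' @param q A unit [quat()].
#' @return The conjugate quaternion.
#' @export
quat_conjugate <- function(q) {
  quat(q[[1L]], -q[[2L]], -q[[3L]], -q[[4L]], normalize = FALSE)
}

#' Hamilton product of two quaternions
#'
#' Composes rotations: `quat_multiply(a, b)` applies `b` first, then `a`.
#' The result is renormalised so repeated composition cannot drift off the
#' unit sphere.
#'
#' @param a,b Unit quaternions.
#' @return Unit quaternion `a %*% b` (Hamilton product).
#' @export
quat_multiply <- function(a, b) {
  w1 <- a[[1L]]; x1 <- a[[2L]]; y1 <- a[[3L]]; z1 <- a[[4L]]
  w2 <- b[[1L]]; x2 <- b[[2L]]; y2 <- b[[3L]]; z2 <- b[[4L]]
  quat(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2
  )
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Applies the rotation `q v q*`; for a world-from-body quaternion this takes
#' body-frame coordinates to world-frame coordinates. Rotation is an isometry:
#' the output norm equals the input norm.
#'
#' @param q Unit quaternion.
#' @param v Numeric 3-vector.
#' @return The rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  stopifnot(length(v) == 3L, all(is.finite(v)))
  w <- q[[1L]]; u <- c(q[[2L]], q[[3L]], q[[4L]])
  # q v q* expanded: v' = v + 2 u x (u x v + w v)
  t2 <- cross3(u, v) + w * v
  v + 2 * cross3(u, t2)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Quaternion from an axis-angle rotation
#'
#' @param axis Numeric 3-vector (need not be unit; zero axis with zero angle
#'   gives the identity).
#' @param angle Rotation angle in radians (right-hand rule about `axis`).
#' @return Unit quaternion.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  stopifnot(length(axis) == 3L, is.finite(angle))
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(quat_identity())
  u <- axis / n
  s <- sin(angle / 2)
  quat(cos(angle / 2), u[1L] * s, u[2L] * s, u[3L] * s)
}

#' Shortest-arc quaternion rotating one vector onto another
#'
#' Returns the minimal rotation `q` with `quat_rotate(q, from)` parallel to
#' `to`. For antiparallel inputs the axis is any perpendicular direction
#' (chosen deterministically).
#'
#' @param from,to Nonzero numeric 3-vectors.
#' @return Unit quaternion.
#' @export
quat_between <- function(from, to) {
  nf <- sqrt(sum(from^2)); nt <- sqrt(sum(to^2))
  if (nf < 1e-12 || nt < 1e-12) stop("quat_between needs nonzero vectors")
  f <- from / nf; t <- to / nt
  d <- sum(f * t)
  if (d > 1 - 1e-12) return(quat_identity())
  if (d < -1 + 1e-12) {
    # 180 degrees: pick a stable perpendicular axis
    ax <- cross3(f, c(1, 0, 0))
    if (sum(ax^2) < 1e-12) ax <- cross3(f, c(0, 1, 0))
    return(quat_from_axis_angle(ax, pi))
  }
  axis <- cross3(f, t)
  quat_from_axis_angle(axis, acos(max(-1, min(1, d))))
}

#' Advance a quaternion by a body-frame angular rate
#'
#' One step of gyroscope strapdown integration: the attitude is post-composed
#' with the axis-angle rotation `omega * dt` expressed in the body frame,
#' `q <- q %*% exp(omega dt / 2)`.
#'
#' @param q Current world-from-body unit quaternion.
#' @param omega Angular rate, rad/s, body frame, length 3.
#' @param dt Time step in seconds, `> 0`.
#' @return Updated unit quaternion.
#' @export
integrate_gyro <- function(q, omega, dt) {
  stopifnot(length(omega) == 3L, is.finite(dt), dt > 0)
  angle <- sqrt(sum(omega^2)) * dt
  if (angle == 0) return(q)
  quat_multiply(q, quat_from_axis_angle(omega, angle))
}

#' Complementary-filter tilt correction
#'
#' Nudges the attitude toward agreement with the accelerometer: the body-frame
#' acceleration is rotated into the world frame and the attitude is
#' pre-composed with a fraction `gain` of the shortest rotation that would
#' align it with +Y (the gravity direction). `gain = 0` leaves `q` unchanged,
#' `gain = 1` aligns fully in one step. A zero accelerometer sample carries no
#' gravity information, so the correction is skipped with a warning.
#'
#' @param q World-from-body unit quaternion.
#' @param accel_body Accelerometer sample, m/s^2, body frame, length 3.
#' @param gain Accelerometer trust per step, in `[0, 1]`.
#' @return Corrected unit quaternion.
#' @export
tilt_correct <- function(q, accel_body, gain) {
  stopifnot(length(accel_body) == 3L, is.finite(gain), gain >= 0, gain <= 1)
  if (sqrt(sum(accel_body^2)) < 1e-9) {
    warning("zero acceleration sample: tilt correction skipped")
    return(q)
  }
  if (gain == 0) return(q)
  a_world <- quat_rotate(q, accel_body)
  full <- quat_between(a_world, c(0, 1, 0))
  angle <- 2 * acos(max(-1, min(1, abs(full[[1L]]))))
  if (angle < 1e-12) return(q)
  axis <- c(full[[2L]], full[[3L]], full[[4L]])
  if (full[[1L]] < 0) axis <- -axis   # keep the short way round
  quat_multiply(quat_from_axis_angle(axis, gain * angle), q)
}
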