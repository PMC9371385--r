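#' Track 3-DOF orientation with a gyro + accelerometer complementary filter
#'
#' Estimates a world-from-body rotation quaternion at every sample. The filter
#' trusts the gyroscope at high frequency (strapdown integration of angular
#' rate) and the accelerometer at low frequency (a small tilt correction per
#' step pulling the world-frame image of the measured acceleration toward the
#' +Y gravity direction). The first quaternion is initialised from the first
#' accelerometer sample alone — gravity alignment with yaw fixed at 0. Heading
#' about the gravity axis is unobservable without a magnetometer and is left
#' to drift.
#'
#' @param recording An [imu_recording()].
#' @param gain Accelerometer trust per step, in `[0, 1]`. The default 0.02 at
#'   a 50 Hz operating rate corrects tilt with a time constant of roughly one
#'   second — slow enough that proper acceleration during turns does not bend
#'   the attitude, fast enough to absorb gyro drift and pocket re-orientations
#'   within seconds.
#' @return An `"orientation_track"`: an n x 4 matrix of unit quaternions
#'   (columns `w, x, y, z`), one row per sample.
#' @seealso [to_world()] to apply the track to the accelerometer channels.
#' @export
track_orientation <- function(recording, gain = 0.02) {
  stopifnot(inherits(recording, "imu_recording"),
            is.finite(gain), gain >= 0, gain <= 1)
  n <- length(recording$time)
  out <- matrix(NA_real_, n, 4L, dimnames = list(NULL, c("w", "x", "y", "z")))
  q <- quat_between(recording$accel[1L, ], c(0, 1, 0))
  out[1L, ] <- unclass(q)
  dts <- diff(recording$time)
  for (i in seq_len(n - 1L)) {
    q <- integrate_gyro(q, recording$gyro[i + 1L, ], dts[i])
    q <- tilt_correct(q, recording$accel[i + 1L, ], gain)
    out[i + 1L, ] <- unclass(q)
  }
  structure(out, class = "orientation_track")
}

#' Rotate a recording into the gravity-aligned world frame
#'
#' Applies the per-sample attitude to the accelerometer channels so that
#' gravity is isolated on the world Y axis and proper acceleration lives on X
#' and Z; mid-session phone re-orientations then leave the world-frame
#' channels unchanged. Gyroscope channels are passed through unrotated.
#'
#' @param recording An [imu_recording()].
#' @param track An `orientation_track` from [track_orientation()], same length
#'   as the recording.
#' @return A `"world_frame_recording"`: list with `time`, `accel_world`
#'   (n x 3, m/s^2, gravity along +Y), `gyro` (pass-through), `sample_rate`.
#' @export
to_world <- function(recording, track) {
  stopifnot(inherits(recording, "imu_recording"))
  if (nrow(track) != length(recording$time))
    stop("orientation track length (", nrow(track),
         ") does not match recording length (", length(recording$time), ")")
  n <- length(recording$time)
  aw <- matrix(NA_real_, n, 3L,
               dimnames = list(NULL, c("acc_x", "acc_y", "acc_z")))
  for (i in seq_len(n)) {
    q <- quat(track[i, 1L], track[i, 2L], track[i, 3L], track[i, 4L],
              normalize = FALSE)
    aw[i, ] <- quat_rotate(q, recording$accel[i, ])
  }
  structure(list(time = recording$time, accel_world = aw,
                 gyro = recording$gyro, sample_rate = recording$sample_rate),
            class = "world_frame_recording")
}

#' @export
print.world_frame_recording <- function(x, ...) {
  cat(sprintf("world-frame recording: %d samples, mean Y accel %.3f m/s^2\n",
              length(x$time), mean(x$accel_world[, 2L])))
  invisible(x)
}
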