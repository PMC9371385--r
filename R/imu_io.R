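#' IMU recording container
#'
#' A six-axis inertial recording: timestamps (seconds, strictly increasing),
#' tri-axial accelerometer (m/s^2) and tri-axial gyroscope (rad/s), both in
#' the sensor-fixed body frame.
#'
#' @param time Numeric vector of timestamps in seconds, strictly increasing,
#'   length >= 2.
#' @param accel n x 3 numeric matrix of accelerometer samples (m/s^2).
#' @param gyro n x 3 numeric matrix of gyroscope samples (rad/s).
#' @param sample_rate Nominal sampling rate in Hz; if `NULL`, estimated as the
#'   median reciprocal timestep.
#' @return An object of class `"imu_recording"`: a list with elements `time`,
#'   `accel`, `gyro`, `sample_rate`.
#' @examples
#' t <- seq(0, 1, by = 0.02)
#' rec <- imu_recording(t, matrix(c(0, 9.81, 0), length(t), 3, byrow = TRUE),
#'                      matrix(0, length(t), 3))
#' rec$sample_rate
#' @export
imu_recording <- function(time, accel, gyro, sample_rate = NULL) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(time)
  if (n < 2L) stop("an IMU recording needs at least 2 samples, got ", n)
  if (!all(is.finite(time))) stop("timestamps must be finite")
  bad <- which(diff(time) <= 0)
  if (length(bad))
    stop("timestamps must be strictly increasing; first violation at row ",
         bad[1L] + 1L)
  if (nrow(accel) != n || nrow(gyro) != n)
    stop("accel/gyro must have one row per timestamp (", n, ")")
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stop("accel and gyro must have 3 columns")
  if (!all(is.finite(accel)) || !all(is.finite(gyro)))
    stop("sensor channels must be finite")
  if (is.null(sample_rate)) sample_rate <- stats::median(1 / diff(time))
  colnames(accel) <- c("acc_x", "acc_y", "acc_z")
  colnames(gyro) <- c("gyr_x", "gyr_y", "gyr_z")
  structure(list(time = as.numeric(time), accel = accel, gyro = gyro,
                 sample_rate = sample_rate),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("IMU recording: %d samples, %.2f s at ~%.1f Hz\n",
              length(x$time), diff(range(x$time)), x$sample_rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An [imu_recording()].
#' @export
imu_duration <- function(recording) diff(range(recording$time))

#' Activity segment list
#'
#' Labeled half-open time intervals `[start, end)` with labels `Skiing` or
#' `Not_Skiing`.
#'
#' @param start,end Numeric vectors, seconds, `start < end` elementwise.
#' @param label Character vector of labels, each `"Skiing"` or `"Not_Skiing"`.
#' @return A data.frame of class `"activity_segments"` with columns
#'   `start`, `end`, `label`.
#' @export
activity_segments <- function(start = numeric(), end = numeric(),
                              label = character()) {
  stopifnot(length(start) == length(end), length(start) == length(label))
  label <- as.character(label)
  bad <- setdiff(unique(label), c("Skiing", "Not_Skiing"))
  if (length(bad))
    stop("unknown activity label(s): ", paste(bad, collapse = ", "),
         " (allowed: Skiing, Not_Skiing)")
  if (any(start >= end))
    stop("segment start must be < end (row ",
         which(start >= end)[1L], ")")
  structure(data.frame(start = as.numeric(start), end = as.numeric(end),
                       label = label, stringsAsFactors = FALSE),
            class = c("activity_segments", "data.frame"))
}

#' Read an IMU recording from delimited text
#'
#' Expects a comma-separated UTF-8 file with a header row naming the columns
#' `time_s, acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z` (any order). The nominal
#' sample rate is estimated as the median reciprocal timestep.
#'
#' @param path Path to the CSV file.
#' @return An [imu_recording()].
#' @seealso [write_imu_csv()]
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("IMU file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(df) < 2L)
    stop("IMU file ", path, " has fewer than 2 data rows")
  imu_recording(df$time_s,
                as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
                as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]))
}

#' Write an IMU recording as delimited text
#'
#' Numeric values are written with 9 significant digits, enough for a
#' read/write round trip to reproduce the signal to within formatting
#' precision.
#'
#' @param recording An [imu_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(recording, path) {
  df <- data.frame(time_s = recording$time, recording$accel, recording$gyro)
  fmt <- vapply(df, function(col) formatC(col, digits = 9, format = "g"),
                character(nrow(df)))
  utils::write.table(fmt, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = names(df))
  invisible(path)
}

#' Read / write activity segments
#'
#' Segment files are CSV with header `start_s, end_s, label`; labels must be
#' `Skiing` or `Not_Skiing` and every row must satisfy `start_s < end_s`.
#' An empty file with just the header yields an empty segment list.
#'
#' @param path File path.
#' @return For `read_segments`, an [activity_segments()] data.frame.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("start_s", "end_s", "label"), names(df))
  if (length(miss))
    stop("segment file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  activity_segments(df$start_s, df$end_s, df$label)
}

#' @rdname read_segments
#' @param segments An [activity_segments()] data.frame.
#' @export
write_segments <- function(segments, path) {
  df <- data.frame(start_s = formatC(segments$start, digits = 9, format = "g"),
                   end_s = formatC(segments$end, digits = 9, format = "g"),
                   label = segments$label)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Downsample a recording to a uniform rate
#'
#' Resamples all six channels by linear interpolation onto uniform timestamps
#' starting at the first sample. Only downsampling is supported: interpolation
#' cannot create bandwidth, so `target_rate` must not exceed the source rate.
#' Running a day-long 500 Hz recording at 50 Hz is the intended use: 50 Hz
#' retains the full content of human-movement signals at a tenth of the cost.
#'
#' @param recording An [imu_recording()].
#' @param target_rate Target rate in Hz, `0 < target_rate <= ` source rate.
#' @return An [imu_recording()] with uniform timestamps at `target_rate`.
#' @export
resample_imu <- function(recording, target_rate) {
  stopifnot(is.finite(target_rate), target_rate > 0)
  if (target_rate > recording$sample_rate * (1 + 1e-9))
    stop("resample_imu only downsamples: target ", target_rate,
         " Hz exceeds source ~", round(recording$sample_rate, 3), " Hz")
  t0 <- recording$time[1L]
  t1 <- recording$time[length(recording$time)]
  new_t <- seq(t0, t1 + 1e-12, by = 1 / target_rate)
  interp <- function(col) stats::approx(recording$time, col, xout = new_t,
                                        rule = 2)$y
  imu_recording(new_t,
                apply(recording$accel, 2L, interp),
                apply(recording$gyro, 2L, interp),
                sample_rate = target_rate)
}
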