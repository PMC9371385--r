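.G <- 9.81  # m/s^2, world frame is Y-up: gravity vector is (0, .G, 0)

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic skiing session
#'
#' Describes a full session as the pipeline assumes it: long gravity-dominated
#' idle phases (lift rides, standing around) interrupted by skiing runs of at
#' least 30 s that carry periodic turn oscillations, with optional abrupt
#' phone re-orientations mid-session (phone checked and pocketed differently)
#' and optional short semi-skiing amplitude ramps at run boundaries.
#'
#' @param duration Session length in seconds.
#' @param runs `data.frame` with one row per skiing run and columns `start`
#'   (s), `duration` (s, >= 30), `turn_frequency` (Hz, turn cycles; short
#'   turns near 1 Hz, long carved turns near 0.3 Hz), `turn_amplitude`
#'   (m/s^2, lateral acceleration amplitude). Runs must be non-overlapping
#'   and lie within `[0, duration)`.
#' @param idle_noise_sd,run_noise_sd Additive white accelerometer noise SD
#'   (m/s^2) outside and inside runs.
#' @param orientation_events Optional `data.frame` with columns `time` (s) and
#'   `w, x, y, z` (unit quaternion): at each `time` the phone attitude jumps
#'   to the new orientation.
#' @param orientation Initial phone attitude as a [quat()]; applied to the
#'   gravity vector to produce the body-frame accelerometer reading.
#' @param transition_ramp Semi-skiing ramp length in seconds (0 disables):
#'   turn amplitude ramps linearly over this span at each run boundary.
#' @param sample_rate Sampling rate in Hz.
#' @param seed Integer RNG seed; identical seeds give bit-identical sessions.
#' @return A validated list of class `"session_spec"`.
#' @export
session_spec <- function(duration,
                         runs = data.frame(start = numeric(),
                                           duration = numeric(),
                                           turn_frequency = numeric(),
                                           turn_amplitude = numeric()),
                         idle_noise_sd = 0.3,
                         run_noise_sd = 0.5,
                         orientation_events = NULL,
                         orientation = quat_identity(),
                         transition_ramp = 0,
                         sample_rate = 50,
                         seed = 1L) {
  stopifnot(is.finite(duration), duration > 0,
            is.finite(sample_rate), sample_rate > 0,
            idle_noise_sd >= 0, run_noise_sd >= 0, transition_ramp >= 0)
  runs <- as.data.frame(runs)
  need <- c("start", "duration", "turn_frequency", "turn_amplitude")
  if (!all(need %in% names(runs)))
    stop("runs must have columns ", paste(need, collapse = ", "))
  if (nrow(runs)) {
    if (any(runs$duration <= 0)) stop("run durations must be positive")
    if (any(runs$start < 0 | runs$start + runs$duration > duration))
      stop("runs must lie within [0, duration)")
    o <- order(runs$start)
    runs <- runs[o, , drop = FALSE]
    ends <- runs$start + runs$duration
    if (nrow(runs) > 1L && any(runs$start[-1L] < ends[-nrow(runs)]))
      stop("runs must not overlap")
  }
  stopifnot_unit_quat(orientation)
  if (!is.null(orientation_events)) {
    orientation_events <- as.data.frame(orientation_events)
    stopifnot(all(c("time", "w", "x", "y", "z") %in% names(orientation_events)))
  }
  structure(list(duration = duration, runs = runs,
                 idle_noise_sd = idle_noise_sd, run_noise_sd = run_noise_sd,
                 orientation_events = orientation_events,
                 orientation = orientation,
                 transition_ramp = transition_ramp,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "session_spec")
}

#' Generate a synthetic session with ground truth
#'
#' Builds the body-frame six-axis signal a pocketed phone would record over
#' the session described by `spec`. The accelerometer reads the phone-attitude
#' rotation of gravity everywhere; inside runs a quadrature pair of sinusoids
#' at the run's turn frequency is superposed on the lateral and vertical body
#' axes, emulating periodic carved/parallel turns, and the gyroscope carries a
#' matching sinusoidal roll rate. White noise is added throughout
#' (`run_noise_sd` inside runs, `idle_noise_sd` outside; gyro noise is fixed
#' at 0.02 rad/s). Phone re-orientation events flip the attitude abruptly.
#'
#' @param spec A [session_spec()].
#' @return A list with elements `recording` (an [imu_recording()]) and
#'   `truth` (an [activity_segments()] partition of `[0, duration)`, runs
#'   labeled `Skiing`, the complement `Not_Skiing`).
#' @export
generate_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1L) / spec$sample_rate

  # per-sample phone attitude (piecewise constant across orientation events)
  atts <- list(spec$orientation)
  att_times <- 0
  if (!is.null(spec$orientation_events) && nrow(spec$orientation_events)) {
    ev <- spec$orientation_events[order(spec$orientation_events$time), ,
                                  drop = FALSE]
    for (k in seq_len(nrow(ev))) {
      atts[[length(atts) + 1L]] <- quat(ev$w[k], ev$x[k], ev$y[k], ev$z[k])
      att_times <- c(att_times, ev$time[k])
    }
  }
  att_idx <- findInterval(t, att_times)

  accel <- matrix(0, n, 3L)
  gyro <- matrix(0, n, 3L)
  grav_body <- t(vapply(atts, function(q) quat_rotate(q, c(0, .G, 0)),
                        numeric(3L)))
  accel[] <- grav_body[att_idx, ]

  in_run <- rep(FALSE, n)
  for (k in seq_len(nrow(spec$runs))) {
    r <- spec$runs[k, ]
    idx <- which(t >= r$start & t < r$start + r$duration)
    in_run[idx] <- TRUE
    tt <- t[idx] - r$start
    amp <- rep(r$turn_amplitude, length(idx))
    if (spec$transition_ramp > 0) {
      ramp <- spec$transition_ramp
      amp <- amp * pmin(1, tt / ramp, (r$duration - tt) / ramp)
    }
    ph <- 2 * pi * r$turn_frequency * tt
    accel[idx, 1L] <- accel[idx, 1L] + amp * sin(ph)   # lateral
    accel[idx, 2L] <- accel[idx, 2L] + amp * cos(ph)   # vertical, quadrature
    # roll rate consistent with the lateral oscillation
    gyro[idx, 3L] <- gyro[idx, 3L] + 0.3 * sin(ph)
  }

  with_seed(spec$seed, {
    sdv <- ifelse(in_run, spec$run_noise_sd, spec$idle_noise_sd)
    accel <- accel + matrix(stats::rnorm(3L * n, sd = rep(sdv, 3L)), n, 3L)
    gyro <- gyro + matrix(stats::rnorm(3L * n, sd = 0.02), n, 3L)
  })

  truth <- runs_to_truth(spec$runs, spec$duration)
  list(recording = imu_recording(t, accel, gyro,
                                 sample_rate = spec$sample_rate),
       truth = truth)
}

runs_to_truth <- function(runs, duration) {
  if (!nrow(runs))
    return(activity_segments(0, duration, "Not_Skiing"))
  starts <- c(); ends <- c(); labels <- c()
  cur <- 0
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- s + runs$duration[k]
    if (s > cur) {
      starts <- c(starts, cur); ends <- c(ends, s)
      labels <- c(labels, "Not_Skiing")
    }
    starts <- c(starts, s); ends <- c(ends, e); labels <- c(labels, "Skiing")
    cur <- e
  }
  if (cur < duration) {
    starts <- c(starts, cur); ends <- c(ends, duration)
    labels <- c(labels, "Not_Skiing")
  }
  activity_segments(starts, ends, labels)
}

#' Generate a static (motionless phone) recording
#'
#' Fixture for gravity-isolation checks: the accelerometer reads the given
#' attitude applied to the gravity vector plus white noise, the gyroscope is
#' white noise about zero.
#'
#' @param orientation Phone attitude as a unit [quat()].
#' @param duration Seconds.
#' @param sample_rate Hz.
#' @param noise_sd Accelerometer noise SD in m/s^2.
#' @param gyro_noise_sd Gyroscope noise SD in rad/s.
#' @param seed Optional integer seed.
#' @return An [imu_recording()].
#' @export
generate_static <- function(orientation, duration, sample_rate,
                            noise_sd = 0, gyro_noise_sd = 0.01 * (noise_sd > 0),
                            seed = NULL) {
  stopifnot_unit_quat(orientation)
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  g_body <- quat_rotate(orientation, c(0, .G, 0))
  accel <- matrix(g_body, n, 3L, byrow = TRUE)
  gyro <- matrix(0, n, 3L)
  with_seed(seed, {
    if (noise_sd > 0)
      accel <- accel + matrix(stats::rnorm(3L * n, sd = noise_sd), n, 3L)
    if (gyro_noise_sd > 0)
      gyro <- gyro + matrix(stats::rnorm(3L * n, sd = gyro_noise_sd), n, 3L)
  })
  imu_recording(t, accel, gyro, sample_rate = sample_rate)
}

#' Draw a randomised session specification
#'
#' Convenience wrapper producing a day-of-skiing-like session: `n_runs` runs
#' of 40-90 s separated by 60-120 s idle gaps (lift rides, queueing), turn
#' frequencies in [0.3, 1.2] Hz spanning long carved to short turns, default
#' noise levels, and a random initial phone attitude.
#'
#' @param n_runs Number of skiing runs.
#' @param seed Integer seed driving both the layout and the noise.
#' @param turn_amplitude Turn oscillation amplitude, m/s^2.
#' @param ... Passed on to [session_spec()].
#' @return A [session_spec()].
#' @export
random_session_spec <- function(n_runs, seed, turn_amplitude = 3, ...) {
  with_seed(seed, {
    gaps <- stats::runif(n_runs + 1L, 60, 120)
    durs <- stats::runif(n_runs, 40, 90)
    starts <- cumsum(gaps[seq_len(n_runs)]) + c(0, cumsum(durs))[seq_len(n_runs)]
    runs <- data.frame(start = starts, duration = durs,
                       turn_frequency = stats::runif(n_runs, 0.3, 1.2),
                       turn_amplitude = turn_amplitude)
    axis <- stats::rnorm(3L)
    ori <- quat_from_axis_angle(axis, stats::runif(1L, 0, pi))
    session_spec(duration = sum(gaps) + sum(durs), runs = runs,
                 orientation = ori, seed = seed, ...)
  })
}
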