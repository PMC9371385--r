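#' Smoothing configuration for the two-stage filter
#'
#' @param ma_window Moving-average window length in seconds (> 0). Default
#'   0.5 s: long enough to average pocket shake, short enough to keep turn
#'   cycles (<= 1.5 Hz) intact.
#' @param lp_cutoff Butterworth low-pass cutoff in Hz. Default 3 Hz keeps all
#'   plausible turn frequencies with margin and removes the rest.
#' @param lp_order Butterworth order, >= 1. Default 4.
#' @return A list of class `"filter_config"`.
#' @export
filter_config <- function(ma_window = 0.5, lp_cutoff = 3, lp_order = 4L) {
  stopifnot(is.finite(ma_window), ma_window > 0,
            is.finite(lp_cutoff), lp_cutoff > 0,
            lp_order >= 1)
  structure(list(ma_window = ma_window, lp_cutoff = lp_cutoff,
                 lp_order = as.integer(lp_order)),
            class = "filter_config")
}

#' Centered moving average
#'
#' Smooths with a centered window of `window * rate` samples (rounded to the
#' nearest odd count); near the edges the window shrinks to the available
#' samples, so the output has the input's length and constants pass through
#' unchanged (DC gain 1).
#'
#' @param x Numeric series.
#' @param window Window length in seconds, with `window * rate >= 1`.
#' @param rate Sampling rate in Hz.
#' @return Smoothed series, same length as `x`.
#' @export
moving_average <- function(x, window, rate) {
  if (!is.finite(window) || window <= 0) stop("window must be positive")
  stopifnot(is.finite(rate), rate > 0)
  k <- max(1L, round(window * rate))
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  h <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Zero-phase Butterworth low-pass
#'
#' Filters forward and backward (squared magnitude response, zero phase) so
#' smoothed features stay aligned in time with the raw signal. The series is
#' extended by reflection at both ends before filtering to suppress edge
#' transients; DC gain is 1.
#'
#' @param x Numeric series.
#' @param cutoff Cutoff frequency in Hz, `< rate / 2`.
#' @param order Filter order.
#' @param rate Sampling rate in Hz.
#' @return Filtered series, same length as `x`.
#' @export
low_pass <- function(x, cutoff, order, rate) {
  stopifnot(is.finite(cutoff), cutoff > 0, is.finite(rate), rate > 0)
  if (cutoff >= rate / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist rate (",
         rate / 2, " Hz)")
  n <- length(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  # pad generously: the forward pass starts from zero state and its
  # transient must die inside the padding, not inside the signal
  pad <- min(n - 1L, max(3L * order, ceiling(10 * rate / cutoff)))
  xe <- c(2 * x[1L] - x[pad + 1L - seq_len(pad) + 1L], x,
          2 * x[n] - x[n - seq_len(pad)])
  y <- signal::filter(bf, xe)
  y <- rev(signal::filter(bf, rev(y)))
  y[pad + seq_len(n)]
}

#' Two-stage smoothing of a world-frame recording
#'
#' Applies the moving average and then the zero-phase low-pass to all six
#' world-frame channels (rotated accelerometer and pass-through gyroscope).
#' The order is fixed: the moving average first suppresses broadband pocket
#' shake, then the low-pass leaves a clean activity pattern. The two stages
#' do not commute in general.
#'
#' @param wrec A `world_frame_recording` from [to_world()].
#' @param cfg A [filter_config()].
#' @return A `world_frame_recording` with filtered channels.
#' @export
two_stage_filter <- function(wrec, cfg = filter_config()) {
  stopifnot(inherits(wrec, "world_frame_recording"),
            inherits(cfg, "filter_config"))
  smooth <- function(col) {
    low_pass(moving_average(col, cfg$ma_window, wrec$sample_rate),
             cfg$lp_cutoff, cfg$lp_order, wrec$sample_rate)
  }
  out <- wrec
  out$accel_world <- apply(wrec$accel_world, 2L, smooth)
  out$gyro <- apply(wrec$gyro, 2L, smooth)
  colnames(out$accel_world) <- colnames(wrec$accel_world)
  colnames(out$gyro) <- colnames(wrec$gyro)
  out
}
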