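#' Windowing configuration
#'
#' @param window_size Window length in seconds. The model-selection grid
#'   spans 3-10 s; the shipped default is 8 s.
#' @param sliding_rate Step between window starts as a fraction of the window
#'   length, in `(0, 1]`; 1.0 means disjoint windows (no overlap), 0.5 means
#'   50% overlap. Overlap = 1 - sliding_rate.
#' @return A list of class `"window_config"`.
#' @export
window_config <- function(window_size = 8, sliding_rate = 0.5) {
  stopifnot(is.finite(window_size), window_size > 0,
            is.finite(sliding_rate), sliding_rate > 0, sliding_rate <= 1)
  structure(list(window_size = window_size, sliding_rate = sliding_rate),
            class = "window_config")
}

#' Cut a filtered recording into sliding windows
#'
#' Windows start at `0, step, 2 step, ...` with `step = sliding_rate *
#' window_size`; a trailing window that would run past the recording is
#' dropped, giving `floor((duration - window_size) / step) + 1` windows. Each
#' window holds the samples with time in `[start, start + window_size)` for
#' all six channels.
#'
#' @param wrec A `world_frame_recording` (typically after
#'   [two_stage_filter()]).
#' @param cfg A [window_config()].
#' @return List of windows; each has `start`, `end`, and a `channels` matrix
#'   (samples x 6, columns `acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`).
#'   A recording shorter than one window yields an empty list with a warning.
#' @export
segment_windows <- function(wrec, cfg) {
  stopifnot(inherits(cfg, "window_config"))
  t <- wrec$time
  t0 <- t[1L]
  # duration counts whole sample periods: n samples at rate r cover n/r s
  duration <- t[length(t)] - t0 + stats::median(diff(t))
  ws <- cfg$window_size
  if (duration < ws) {
    warning("recording (", round(duration, 3), " s) shorter than one ",
            ws, " s window: no windows")
    return(list())
  }
  step <- cfg$sliding_rate * ws
  n_win <- floor((duration - ws) / step + 1e-9) + 1L
  chans <- cbind(wrec$accel_world, wrec$gyro)
  lapply(seq_len(n_win) - 1L, function(i) {
    s <- t0 + i * step
    idx <- which(t >= s - 1e-9 & t < s + ws - 1e-9)
    list(start = s, end = s + ws, channels = chans[idx, , drop = FALSE])
  })
}

#' Normalized autocorrelation at nonnegative lags
#'
#' Biased sample autocorrelation `r_k = sum((x_t - m)(x_{t+k} - m)) /
#' sum((x_t - m)^2)` for lags `0 .. n-1`, so `r_0 = 1`. Periodic signals show
#' a secondary peak at their period lag, which is what makes the
#' autocorrelation domain separate rhythmic skiing from idle noise. A
#' constant series has no fluctuation to correlate; it is defined as 1 at lag
#' 0 and 0 beyond.
#'
#' @param x Numeric series, length >= 2, finite.
#' @return Numeric vector of length `length(x)`, lag 0 first.
#' @export
autocorrelate <- function(x) {
  n <- length(x)
  stopifnot(n >= 2L, all(is.finite(x)))
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom < 1e-24) return(c(1, rep(0, n - 1L)))
  r <- stats::acf(x, lag.max = n - 1L, plot = FALSE, demean = TRUE)$acf[, 1L, 1L]
  r
}

#' Level-crossing count
#'
#' Counts sign changes of `x - level` between consecutive samples. Samples
#' exactly at the level inherit the previous sign, so touching the level
#' without crossing does not count.
#'
#' @param x Numeric series.
#' @param level Crossing level.
#' @return Integer count.
#' @export
crossings <- function(x, level) {
  stopifnot(all(is.finite(x)), is.finite(level))
  s <- sign(x - level)
  # zeros inherit the previous nonzero sign
  if (length(s) > 1L) {
    for (i in seq_along(s)[-1L]) if (s[i] == 0) s[i] <- s[i - 1L]
  }
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

window_stats <- function(x) {
  c(mean = mean(x), sd = stats::sd(x), rms = sqrt(mean(x^2)),
    min = min(x), max = max(x), median = stats::median(x),
    variance = stats::var(x), mad = stats::mad(x, constant = 1),
    energy = mean(x^2))
}

window_crossings <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  c(crossings_mean = crossings(x, mean(x)),
    crossings_p25 = crossings(x, q[1L]),
    crossings_p50 = crossings(x, q[2L]),
    crossings_p75 = crossings(x, q[3L]))
}

spectrum_stats <- function(x) {
  sp <- stats::spec.pgram(x, taper = 0, detrend = TRUE, plot = FALSE,
                          fast = FALSE)
  keep <- sp$freq > 0
  c(spec_mean = mean(sp$spec[keep]), spec_median = stats::median(sp$spec[keep]))
}

#' Per-window feature vector
#'
#' For each of the six channels: nine summary statistics (mean, SD, RMS, min,
#' max, median, variance, raw median absolute deviation, energy = mean
#' square) on the raw window and again on its autocorrelation; four
#' level-crossing counts (of the mean and the 25th/50th/75th percentiles) on
#' the raw window and on its autocorrelation; and the mean and median of the
#' periodogram of the detrended window. Plus one signal-magnitude-area value,
#' `SMA = mean(|acc_x| + |acc_y| + |acc_z|)`, over the three accelerometer
#' channels. Columns are named `channel__domain__feature` (domains `raw`,
#' `ac`, `spec`), 169 features in total.
#'
#' @param w A window from [segment_windows()].
#' @return Named numeric vector.
#' @export
window_features <- function(w) {
  if (is.null(w$channels) || nrow(w$channels) < 2L)
    stop("window_features needs a window with at least 2 samples")
  chans <- w$channels
  out <- numeric(0)
  for (ch in colnames(chans)) {
    x <- chans[, ch]
    ac <- autocorrelate(x)
    v <- c(window_stats(x), window_crossings(x),
           window_stats(ac), window_crossings(ac),
           spectrum_stats(x))
    dom <- rep(c("raw", "ac", "spec"), c(13L, 13L, 2L))
    names(v) <- paste(ch, dom, sub("^crossings_", "crossings_", names(v)),
                      sep = "__")
    out <- c(out, v)
  }
  out <- c(out, sma = mean(rowSums(abs(chans[, 1:3, drop = FALSE]))))
  out
}

#' Feature matrix over all windows
#'
#' @param windows List of windows from [segment_windows()].
#' @return A `"feature_matrix"`: numeric matrix (windows x features) with
#'   attributes `starts`, `ends` (window spans, seconds) and `feature_set`
#'   (`"raw"` until normalised).
#' @export
extract_features <- function(windows) {
  if (!length(windows)) stop("no windows to extract features from")
  rows <- lapply(windows, window_features)
  m <- do.call(rbind, rows)
  structure(m,
            starts = vapply(windows, `[[`, numeric(1), "start"),
            ends = vapply(windows, `[[`, numeric(1), "end"),
            feature_set = "raw",
            class = c("feature_matrix", class(m)))
}

#' Min-max normalisation to [-1, 1] (the normalized feature set, NFS)
#'
#' Each column is mapped by `2 (x - min) / (max - min) - 1`, so every
#' non-constant column attains both -1 and 1; constant columns carry no
#' information and map to 0. Statistics are computed over the session being
#' analysed (the unsupervised, single-session use case).
#'
#' @param features A `feature_matrix` from [extract_features()], >= 2 rows.
#' @return A `feature_matrix` with `feature_set = "NFS"`, entries in
#'   `[-1, 1]`.
#' @export
normalize_minmax <- function(features) {
  if (nrow(features) < 2L)
    stop("min-max scaling needs at least 2 windows")
  rng <- apply(features, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  out <- sweep(features, 2L, rng[1L, ], "-")
  nz <- span > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, span[nz], "/") * 2 - 1
  out[, !nz] <- 0
  keep_fm_attrs(out, features, "NFS")
}

keep_fm_attrs <- function(m, src, feature_set) {
  structure(as.matrix(m),
            starts = attr(src, "starts"), ends = attr(src, "ends"),
            feature_set = feature_set,
            class = c("feature_matrix", "matrix", "array"))
}

#' Principal-component reduction of the NFS
#'
#' Projects the normalised features onto the leading principal components,
#' keeping the smallest number whose cumulative variance share reaches
#' `variance_kept`. Component signs follow a deterministic convention: the
#' loading of largest magnitude in each component is positive.
#'
#' @param nfs A normalised `feature_matrix` (see [normalize_minmax()]).
#' @param variance_kept Fraction of total variance to retain, in `(0, 1]`.
#' @return A `feature_matrix` of component scores, `feature_set = "PCA"`,
#'   columns `PC1, PC2, ...`.
#' @export
pca_reduce <- function(nfs, variance_kept = 0.95) {
  if (!(is.finite(variance_kept) && variance_kept > 0 && variance_kept <= 1))
    stop("variance_kept must be in (0, 1]")
  if (nrow(nfs) < 2L) stop("PCA needs at least 2 windows")
  pc <- stats::prcomp(unclass(nfs), center = TRUE, scale. = FALSE)
  vshare <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(vshare >= variance_kept - 1e-12)[1L]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  scores <- sweep(scores, 2L, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  keep_fm_attrs(scores, nfs, "PCA")
}

#' Write a feature matrix as CSV for inspection
#'
#' @param features A `feature_matrix`.
#' @param path Output path.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(start_s = attr(features, "starts"),
                   end_s = attr(features, "ends"),
                   unclass(features), check.names = FALSE)
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
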