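#' Full pipeline configuration
#'
#' Bundles the per-stage settings. The shipped defaults are the pipeline's
#' recommended operating point: 50 Hz operating rate, k-means on the
#' PCA-reduced feature set, 8 s windows stepped at half a window (50%
#' overlap), 30 s minimum activity duration.
#'
#' @param operating_rate Rate (Hz) the recording is downsampled to before
#'   analysis; `NULL` keeps the native rate.
#' @param orientation_gain Complementary-filter accelerometer trust per step.
#' @param filter A [filter_config()].
#' @param window A [window_config()].
#' @param feature_set `"PCA"` or `"NFS"`.
#' @param variance_kept PCA variance fraction retained.
#' @param cluster A [cluster_config()].
#' @param min_duration Minimum Skiing activity duration, seconds.
#' @param seed Top-level integer seed fanned out to the stochastic stages.
#' @return A list of class `"ski_config"`.
#' @export
ski_config <- function(operating_rate = 50,
                       orientation_gain = 0.02,
                       filter = filter_config(),
                       window = window_config(window_size = 8,
                                              sliding_rate = 0.5),
                       feature_set = c("PCA", "NFS"),
                       variance_kept = 0.95,
                       cluster = cluster_config("kmeans"),
                       min_duration = 30,
                       seed = 1L) {
  feature_set <- match.arg(feature_set)
  stopifnot(inherits(filter, "filter_config"),
            inherits(window, "window_config"),
            inherits(cluster, "cluster_config"),
            min_duration >= 0)
  cluster$seed <- as.integer(seed)
  structure(list(operating_rate = operating_rate,
                 orientation_gain = orientation_gain,
                 filter = filter, window = window,
                 feature_set = feature_set, variance_kept = variance_kept,
                 cluster = cluster, min_duration = min_duration,
                 seed = as.integer(seed)),
            class = "ski_config")
}

#' Detect skiing activities in an IMU recording
#'
#' The main fitting function. Runs the unsupervised detection pipeline:
#' downsample to the operating rate, track orientation and rotate the
#' accelerometer into the gravity-aligned world frame, smooth with the
#' two-stage filter, cut into sliding windows and extract
#' time/autocorrelation/spectral features, min-max normalise (and optionally
#' PCA-reduce), cluster the windows into two groups, name the high-energy
#' cluster Skiing, vote windows down to per-sample classes, and drop Skiing
#' stretches shorter than the minimum duration. Deterministic under a fixed
#' `config$seed`.
#'
#' @param recording An [imu_recording()].
#' @param config A [ski_config()].
#' @return An object of class `"ski_segmentation"`: list with `segments`
#'   (final [activity_segments()]), `raw_segments` (before the minimum
#'   duration rule), `labeling` (per-window clusters and classes),
#'   `features` (the clustered `feature_matrix`), `config`, `recording`
#'   (the analysed, downsampled recording), `world` (filtered world-frame
#'   channels).
#' @examples
#' spec <- random_session_spec(n_runs = 2, seed = 7)
#' ses <- generate_session(spec)
#' fit <- detect_skiing(ses$recording, ski_config(seed = 7))
#' fit
#' count_activities(segments(fit))
#' @export
detect_skiing <- function(recording, config = ski_config()) {
  stopifnot(inherits(recording, "imu_recording"),
            inherits(config, "ski_config"))
  rec <- recording
  if (!is.null(config$operating_rate) &&
      config$operating_rate < rec$sample_rate * (1 - 1e-9))
    rec <- resample_imu(rec, config$operating_rate)
  track <- track_orientation(rec, gain = config$orientation_gain)
  world <- to_world(rec, track)
  world <- two_stage_filter(world, config$filter)
  windows <- segment_windows(world, config$window)
  if (!length(windows)) stop("recording too short for one window")
  raw_features <- extract_features(windows)
  nfs <- normalize_minmax(raw_features)
  feats <- if (config$feature_set == "PCA")
    pca_reduce(nfs, config$variance_kept) else nfs
  labeling <- cluster_windows(feats, config$cluster)
  labeling <- map_clusters_to_classes(labeling, raw_features)
  raw_segments <- windows_to_segments(labeling, rec$time)
  segments <- drop_short(raw_segments, config$min_duration)
  structure(list(segments = segments, raw_segments = raw_segments,
                 labeling = labeling, features = feats,
                 config = config, recording = rec, world = world),
            class = "ski_segmentation")
}

#' Extract the detected activity segments
#'
#' @param object A `ski_segmentation` fit.
#' @param ... Unused.
#' @return The final [activity_segments()] data.frame.
#' @export
segments <- function(object, ...) UseMethod("segments")

#' @rdname segments
#' @export
segments.ski_segmentation <- function(object, ...) object$segments

#' @export
print.ski_segmentation <- function(x, ...) {
  n_ski <- count_activities(x$segments)
  tot <- sum(with(x$segments, end - start)[x$segments$label == "Skiing"])
  cat(sprintf(
    "ski_segmentation: %d skiing activit%s (%.1f s total) in %.1f s analysed\n",
    n_ski, if (n_ski == 1) "y" else "ies", tot, imu_duration(x$recording)))
  cat(sprintf("  %s on %s features, %g s windows, sliding rate %g\n",
              x$config$cluster$algorithm, x$config$feature_set,
              x$config$window$window_size, x$config$window$sliding_rate))
  if (x$labeling$degenerate) cat("  note: degenerate single-cluster labeling\n")
  invisible(x)
}

#' @export
summary.ski_segmentation <- function(object, ...) {
  seg <- object$segments
  cat("Detected segments:\n")
  print(data.frame(start_s = round(seg$start, 2), end_s = round(seg$end, 2),
                   duration_s = round(seg$end - seg$start, 2),
                   label = seg$label))
  cat(sprintf("\nWindows: %d (%d labeled Skiing); features: %s (%d columns)\n",
              length(object$labeling$cluster),
              sum(object$labeling$class == "Skiing"),
              object$config$feature_set, ncol(object$features)))
  invisible(object)
}

#' Plot a segmentation over the world-frame signal
#'
#' Draws the filtered world-frame lateral acceleration with detected Skiing
#' segments shaded, the quickest visual check that detected intervals sit on
#' the oscillatory stretches.
#'
#' @param x A `ski_segmentation`.
#' @param channel World-frame channel to draw (default lateral, `acc_x`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ski_segmentation <- function(x, channel = "acc_x", ...) {
  sig <- if (channel %in% colnames(x$world$accel_world))
    x$world$accel_world[, channel] else x$world$gyro[, channel]
  graphics::plot(x$world$time, sig, type = "l", xlab = "time [s]",
                 ylab = paste0(channel, " (world frame)"), ...)
  ski <- x$segments[x$segments$label == "Skiing", , drop = FALSE]
  if (nrow(ski))
    graphics::rect(ski$start, min(sig), ski$end, max(sig),
                   col = grDevices::adjustcolor("forestgreen", 0.2),
                   border = NA)
  invisible(x)
}

#' The model-selection grid of settings
#'
#' Enumerates the full search grid: window sizes 3-10 s crossed with sliding
#' rates `{1.0, 0.8, 0.5, 0.2}` (overlaps 0/20/50/80%), 32 combinations; and
#' three clustering algorithms crossed with two feature sets, 6 models.
#'
#' @param window_sizes,sliding_rates,algorithms,feature_sets Vectors defining
#'   the grid axes; defaults give the full grid.
#' @return A data.frame with one row per setting
#'   (`algorithm, feature_set, window_size, sliding_rate`).
#' @export
grid_settings <- function(window_sizes = 3:10,
                          sliding_rates = c(1.0, 0.8, 0.5, 0.2),
                          algorithms = c("kmeans", "gmm", "ward"),
                          feature_sets = c("NFS", "PCA")) {
  expand.grid(algorithm = algorithms, feature_set = feature_sets,
              window_size = window_sizes, sliding_rate = sliding_rates,
              stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Run the setting grid over labeled sessions
#'
#' Fits every setting on every session and scores it against the session's
#' ground truth; per-setting means and standard deviations across sessions
#' are attached for ranking. Settings are ranked by mean accuracy, ties by
#' ARI then NMI.
#'
#' @param sessions List of sessions, each a list with elements `recording`
#'   (an [imu_recording()]) and `truth` ([activity_segments()]) — the shape
#'   [generate_session()] returns.
#' @param settings A settings data.frame from [grid_settings()].
#' @param base_config A [ski_config()] supplying everything the grid does not
#'   vary (rates, filter, gain, seed).
#' @return A list of class `"ski_grid"`: `results` (one row per setting per
#'   session), `summary` (per-setting mean/SD, ranked).
#' @export
run_grid <- function(sessions, settings = grid_settings(),
                     base_config = ski_config()) {
  stopifnot(length(sessions) > 0, nrow(settings) > 0)
  rows <- vector("list", nrow(settings) * length(sessions))
  k <- 0L
  for (i in seq_len(nrow(settings))) {
    s <- settings[i, ]
    cfg <- base_config
    cfg$window <- window_config(s$window_size, s$sliding_rate)
    cfg$feature_set <- s$feature_set
    cfg$cluster <- cluster_config(s$algorithm, seed = base_config$seed,
                                  restarts = base_config$cluster$restarts)
    for (j in seq_along(sessions)) {
      fit <- detect_skiing(sessions[[j]]$recording, cfg)
      rep_ <- evaluate_segmentation(fit$segments, sessions[[j]]$truth,
                                    fit$recording,
                                    setting = as.list(s))
      row <- report_as_row(rep_)
      row$session <- j
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(
    results[, c("accuracy", "nmi", "ari", "detected_activities")],
    by = results[, c("algorithm", "feature_set", "window_size",
                     "sliding_rate")],
    FUN = mean)
  sds <- stats::aggregate(
    results[, c("accuracy", "nmi", "ari")],
    by = results[, c("algorithm", "feature_set", "window_size",
                     "sliding_rate")],
    FUN = stats::sd)
  names(sds)[5:7] <- c("accuracy_sd", "nmi_sd", "ari_sd")
  smry <- merge(agg, sds)
  smry <- smry[order(-smry$accuracy, -smry$ari, -smry$nmi), ]
  rownames(smry) <- NULL
  structure(list(results = results, summary = smry), class = "ski_grid")
}

#' @export
print.ski_grid <- function(x, n = 5L, ...) {
  cat(sprintf("setting grid: %d settings x %d session(s)\n",
              nrow(x$summary), length(unique(x$results$session))))
  cat("top settings by accuracy (ties: ARI, NMI):\n")
  print(utils::head(x$summary, n), digits = 4)
  invisible(x)
}
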