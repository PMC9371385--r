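#' Clustering configuration
#'
#' The detection stage always asks for two clusters (Skiing vs Not-Skiing);
#' only the algorithm, seed, and number of k-means restarts vary.
#'
#' @param algorithm One of `"kmeans"` (Hartigan-Wong with `restarts` random
#'   starts), `"gmm"` (Gaussian mixture, full covariances), `"ward"`
#'   (agglomerative, Ward linkage on Euclidean distances — deterministic by
#'   construction).
#' @param seed Integer seed making kmeans/gmm deterministic.
#' @param restarts Number of k-means restarts, >= 1.
#' @return A list of class `"cluster_config"`.
#' @export
cluster_config <- function(algorithm = c("kmeans", "gmm", "ward"),
                           seed = 1L, restarts = 10L) {
  algorithm <- match.arg(algorithm)
  stopifnot(restarts >= 1)
  structure(list(algorithm = algorithm, n_clusters = 2L,
                 seed = as.integer(seed), restarts = as.integer(restarts)),
            class = "cluster_config")
}

#' Cluster windows into two groups
#'
#' Runs the configured algorithm on the feature matrix and returns raw
#' cluster ids in `{1, 2}`. If every row is identical the data cannot support
#' two clusters; all windows get id 1 and the labeling is flagged degenerate.
#'
#' @param features A `feature_matrix` (NFS or PCA).
#' @param cfg A [cluster_config()].
#' @importFrom mclust Mclust mclustBIC
#' @return A `"window_labeling"`: list with `cluster` (integer per window),
#'   `starts`, `ends` (window spans), `class` (filled by
#'   [map_clusters_to_classes()]), `degenerate` flag.
#' @export
cluster_windows <- function(features, cfg = cluster_config()) {
  stopifnot(inherits(cfg, "cluster_config"))
  m <- unclass(features)
  attr(m, "starts") <- attr(m, "ends") <- attr(m, "feature_set") <- NULL
  if (nrow(m) < 2L)
    stop("clustering needs at least 2 windows, got ", nrow(m))
  degenerate <- all(apply(m, 2L, function(col) diff(range(col)) == 0))
  if (degenerate) {
    warning("all windows identical: degenerate single cluster")
    cl <- rep(1L, nrow(m))
  } else {
    cl <- switch(cfg$algorithm,
      kmeans = with_seed(cfg$seed,
        stats::kmeans(m, centers = 2L, nstart = cfg$restarts,
                      iter.max = 100L)$cluster),
      gmm = with_seed(cfg$seed, {
        fit <- Mclust(m, G = 2L, modelNames = "VVV", verbose = FALSE)
        if (is.null(fit))  # VVV can fail on low-rank features
          fit <- Mclust(m, G = 2L, verbose = FALSE)
        fit$classification
      }),
      ward = stats::cutree(
        stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2"), k = 2L))
    if (length(unique(cl)) == 1L) degenerate <- TRUE
  }
  structure(list(cluster = as.integer(cl),
                 starts = attr(features, "starts"),
                 ends = attr(features, "ends"),
                 class = NULL, degenerate = degenerate),
            class = "window_labeling")
}

#' Identify which cluster is Skiing
#'
#' Cluster ids are arbitrary; the Skiing cluster is the one with the larger
#' mean raw-window energy summed over the accelerometer channels — turning
#' produces sustained oscillation, idle phases do not. Exact ties fall to the
#' smaller cluster (skiing is the minority class in a day's recording).
#'
#' A two-group clusterer always returns two groups even when the session
#' contains a single activity class, splitting idle windows along slow drift.
#' The mapping therefore accepts the split as two activities only when the
#' clusters are dynamically distinct: the ratio of their mean summed
#' accelerometer variances (a gravity-free measure of movement intensity)
#' must exceed `min_var_ratio`. Otherwise the session is treated as all
#' Not_Skiing, as is a degenerate single-cluster labeling. Turn oscillations
#' raise window variance by orders of magnitude, so the default threshold of
#' 4 is far from both regimes.
#'
#' @param labeling A `window_labeling` from [cluster_windows()].
#' @param features The raw (unnormalised) `feature_matrix` the windows came
#'   from; its `*__raw__energy` and `*__raw__variance` accelerometer columns
#'   drive the decision.
#' @param min_var_ratio Minimum between-cluster accelerometer variance ratio
#'   for the clusters to count as distinct activities.
#' @return The labeling with `class` filled (`"Skiing"` / `"Not_Skiing"`).
#' @export
map_clusters_to_classes <- function(labeling, features, min_var_ratio = 4) {
  stopifnot(inherits(labeling, "window_labeling"))
  if (labeling$degenerate || length(unique(labeling$cluster)) == 1L) {
    labeling$class <- rep("Not_Skiing", length(labeling$cluster))
    return(labeling)
  }
  ecols <- grep("^acc_[xyz]__raw__energy$", colnames(features))
  vcols <- grep("^acc_[xyz]__raw__variance$", colnames(features))
  if (!length(ecols)) stop("features lack raw accelerometer energy columns")
  if (length(vcols)) {
    v <- rowSums(unclass(features)[, vcols, drop = FALSE])
    mv <- c(mean(v[labeling$cluster == 1L]), mean(v[labeling$cluster == 2L]))
    if (min(mv) > 0 && max(mv) / min(mv) < min_var_ratio) {
      labeling$degenerate <- TRUE
      labeling$class <- rep("Not_Skiing", length(labeling$cluster))
      return(labeling)
    }
  }
  energy <- rowSums(unclass(features)[, ecols, drop = FALSE])
  e1 <- mean(energy[labeling$cluster == 1L])
  e2 <- mean(energy[labeling$cluster == 2L])
  ski <- if (e1 > e2) 1L else if (e2 > e1) 2L
    else if (sum(labeling$cluster == 1L) <= sum(labeling$cluster == 2L)) 1L
    else 2L
  labeling$class <- ifelse(labeling$cluster == ski, "Skiing", "Not_Skiing")
  labeling
}

#' Convert labeled windows to activity segments
#'
#' Each time point in the covered span gets the majority class of the windows
#' covering it (ties go to Not_Skiing, the conservative default); maximal
#' constant-class stretches become segments. The returned segments partition
#' `[first window start, last window end)`.
#'
#' @param labeling A class-filled `window_labeling`.
#' @param times Sample timestamps on which to take the per-sample vote
#'   (typically the recording's own timestamps).
#' @return An [activity_segments()] data.frame.
#' @export
windows_to_segments <- function(labeling, times) {
  stopifnot(inherits(labeling, "window_labeling"),
            !is.null(labeling$class))
  span <- c(min(labeling$starts), max(labeling$ends))
  tt <- times[times >= span[1L] & times < span[2L]]
  if (!length(tt)) return(activity_segments())
  votes_ski <- integer(length(tt))
  votes_not <- integer(length(tt))
  for (w in seq_along(labeling$starts)) {
    idx <- tt >= labeling$starts[w] & tt < labeling$ends[w]
    if (labeling$class[w] == "Skiing") votes_ski[idx] <- votes_ski[idx] + 1L
    else votes_not[idx] <- votes_not[idx] + 1L
  }
  cls <- ifelse(votes_ski > votes_not, "Skiing", "Not_Skiing")
  runs_from_samples(tt, cls, span[2L])
}

# collapse a per-sample class sequence into segments; the last segment is
# closed at `end_time`
runs_from_samples <- function(tt, cls, end_time) {
  change <- c(TRUE, cls[-1L] != cls[-length(cls)])
  starts <- tt[change]
  ends <- c(tt[change][-1L], end_time)
  activity_segments(starts, ends, cls[change])
}

#' Enforce the minimum activity duration
#'
#' A skiing run lasts at least 30 s; anything shorter that the clusterer
#' called Skiing is semi-skiing or noise. Such segments are relabeled
#' Not_Skiing (not deleted, so the timeline stays fully covered) and merged
#' with their neighbours.
#'
#' @param segments An [activity_segments()] data.frame, time-ordered.
#' @param min_duration Minimum Skiing duration in seconds (default 30; a
#'   segment of exactly `min_duration` is kept).
#' @return An [activity_segments()] data.frame with every Skiing segment
#'   >= `min_duration` and no two adjacent segments sharing a label.
#' @export
drop_short <- function(segments, min_duration = 30) {
  if (!nrow(segments)) return(segments)
  lab <- segments$label
  short <- lab == "Skiing" & (segments$end - segments$start) < min_duration
  lab[short] <- "Not_Skiing"
  merge_adjacent(activity_segments(segments$start, segments$end, lab))
}

merge_adjacent <- function(segments) {
  if (nrow(segments) < 2L) return(segments)
  keep_start <- c(); keep_end <- c(); keep_lab <- c()
  cs <- segments$start[1L]; ce <- segments$end[1L]; cl <- segments$label[1L]
  for (i in seq_len(nrow(segments))[-1L]) {
    if (segments$label[i] == cl && abs(segments$start[i] - ce) < 1e-9) {
      ce <- segments$end[i]
    } else {
      keep_start <- c(keep_start, cs); keep_end <- c(keep_end, ce)
      keep_lab <- c(keep_lab, cl)
      cs <- segments$start[i]; ce <- segments$end[i]; cl <- segments$label[i]
    }
  }
  keep_start <- c(keep_start, cs); keep_end <- c(keep_end, ce)
  keep_lab <- c(keep_lab, cl)
  activity_segments(keep_start, keep_end, keep_lab)
}

#' Number of detected skiing activities
#'
#' @param segments An [activity_segments()] data.frame.
#' @return Count of Skiing segments.
#' @export
count_activities <- function(segments) sum(segments$label == "Skiing")
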