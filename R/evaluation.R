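#' Expand segments to a per-sample class sequence
#'
#' Evaluation is per sample, against time-labeled ground truth: each
#' timestamp gets the label of the half-open segment `[start, end)` covering
#' it; time not covered by any segment defaults to Not_Skiing.
#'
#' @param times Numeric timestamps (seconds).
#' @param segments An [activity_segments()] data.frame.
#' @return Character vector, one class per timestamp.
#' @export
per_sample_classes <- function(times, segments) {
  out <- rep("Not_Skiing", length(times))
  for (i in seq_len(nrow(segments))) {
    out[times >= segments$start[i] & times < segments$end[i]] <-
      segments$label[i]
  }
  out
}

#' Per-sample accuracy, percent
#'
#' @param pred,truth Equal-length class sequences.
#' @return `100 * mean(pred == truth)`.
#' @export
accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) > 0)
  100 * mean(pred == truth)
}

#' Majority-class baseline accuracy, percent
#'
#' The reference model predicts Not_Skiing everywhere — on a day-long
#' recording most time is lifts and idling, so this baseline is high and any
#' useful detector must beat it. Its NMI and ARI are 0 by construction
#' (a constant labeling carries no information about the truth).
#'
#' @param truth Class sequence.
#' @return Percentage of Not_Skiing samples in `truth`.
#' @export
baseline_accuracy <- function(truth) {
  stopifnot(length(truth) > 0)
  100 * mean(truth == "Not_Skiing")
}

contingency <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  table(a, b)
}

choose2 <- function(n) n * (n - 1) / 2

#' Rand index of two labelings
#'
#' Fraction of sample pairs on which the two labelings agree (placed together
#' in both, or apart in both), computed from the contingency table:
#' `RI = (a + b) / C(N, 2)`.
#'
#' @param a,b Equal-length labelings (any label type), `N >= 2`.
#' @return Value in `[0, 1]`; 1 for identical partitions (up to label names).
#' @export
rand_index <- function(a, b) {
  tab <- contingency(a, b)
  n <- sum(tab)
  s_ij <- sum(choose2(tab))
  s_i <- sum(choose2(rowSums(tab)))
  s_j <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  agree_together <- s_ij
  agree_apart <- total - s_i - s_j + s_ij
  (agree_together + agree_apart) / total
}

#' Adjusted Rand index
#'
#' The Rand index corrected for chance under the permutation model,
#' `ARI = (RI - E[RI]) / (max(RI) - E[RI])`, computed from the contingency
#' table. Identical partitions score 1; independent labelings score 0 in
#' expectation; a constant labeling against a non-constant truth scores 0.
#'
#' @inheritParams rand_index
#' @return Value in `(-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- contingency(a, b)
  n <- sum(tab)
  s_ij <- sum(choose2(tab))
  s_i <- sum(choose2(rowSums(tab)))
  s_j <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- s_i * s_j / total
  max_index <- (s_i + s_j) / 2
  if (abs(max_index - expected) < 1e-12) return(1)  # both partitions trivial
  (s_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information of the two labelings normalised by the geometric mean
#' of their entropies (natural logs; any consistent base gives the same
#' ratio). Identical non-trivial labelings score 1, independent labelings
#' approach 0 with sample size; values below 0 cannot occur. Degenerate
#' cases: both labelings single-cluster is defined as 1, exactly one
#' single-cluster labeling as 0 (zero mutual information); both are flagged
#' via attribute `degenerate`.
#'
#' @inheritParams rand_index
#' @return Value in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  tab <- contingency(a, b)
  n <- sum(tab)
  p_ij <- tab / n
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  h_i <- -sum(ifelse(p_i > 0, p_i * log(p_i), 0))
  h_j <- -sum(ifelse(p_j > 0, p_j * log(p_j), 0))
  if (h_i == 0 && h_j == 0)
    return(structure(1, degenerate = TRUE))
  if (h_i == 0 || h_j == 0)
    return(structure(0, degenerate = TRUE))
  outer_p <- outer(p_i, p_j)
  mi <- sum(ifelse(p_ij > 0, p_ij * log(p_ij / outer_p), 0))
  max(0, mi / sqrt(h_i * h_j))
}

#' Score a predicted segmentation against ground truth
#'
#' Expands both segmentations to per-sample class sequences on the
#' recording's timestamps and computes accuracy, the majority-class baseline,
#' NMI, ARI, and the detected-activity count. When accuracy is high but the
#' clustering metrics are low — the over/under-fitting signature on long,
#' imbalanced sessions — a diagnostic note is attached.
#'
#' @param pred_segments,truth_segments [activity_segments()] data.frames.
#' @param recording The [imu_recording()] they describe (its timestamps are
#'   the evaluation grid).
#' @param setting Optional named list describing the pipeline setting
#'   (algorithm, feature set, window size, sliding rate) carried into the
#'   report.
#' @return A list of class `"evaluation_report"`: `accuracy`,
#'   `baseline_accuracy` (percent), `nmi`, `ari`, `detected_activities`,
#'   `true_activities`, `flags`, `setting`.
#' @export
evaluate_segmentation <- function(pred_segments, truth_segments, recording,
                                  setting = NULL) {
  times <- recording$time
  pred <- per_sample_classes(times, pred_segments)
  truth <- per_sample_classes(times, truth_segments)
  nmi_v <- nmi(truth, pred)
  report <- list(
    accuracy = accuracy(pred, truth),
    baseline_accuracy = baseline_accuracy(truth),
    nmi = as.numeric(nmi_v),
    ari = adjusted_rand_index(truth, pred),
    detected_activities = count_activities(pred_segments),
    true_activities = count_activities(truth_segments),
    flags = character(),
    setting = setting
  )
  if (isTRUE(attr(nmi_v, "degenerate")))
    report$flags <- c(report$flags, "degenerate_labeling")
  if (report$accuracy > 95 && (report$nmi < 0.5 || report$ari < 0.5))
    report$flags <- c(report$flags,
                      "high_accuracy_low_cluster_metrics: possible over/under-fit on an imbalanced session")
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%% (baseline %.2f%%) | NMI %.3f | ARI %.3f | activities %d/%d\n",
    x$accuracy, x$baseline_accuracy, x$nmi, x$ari,
    x$detected_activities, x$true_activities))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Serialise an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param path Output path; `as_csv_row` instead returns a one-row
#'   data.frame for grid aggregation.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report_json
#' @export
report_as_row <- function(report) {
  s <- report$setting
  data.frame(
    algorithm = if (is.null(s$algorithm)) NA_character_ else s$algorithm,
    feature_set = if (is.null(s$feature_set)) NA_character_ else s$feature_set,
    window_size = if (is.null(s$window_size)) NA_real_ else s$window_size,
    sliding_rate = if (is.null(s$sliding_rate)) NA_real_ else s$sliding_rate,
    accuracy = report$accuracy,
    baseline_accuracy = report$baseline_accuracy,
    nmi = report$nmi, ari = report$ari,
    detected_activities = report$detected_activities,
    true_activities = report$true_activities,
    stringsAsFactors = FALSE)
}
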