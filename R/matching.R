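#' Optimally match detections to ground-truth neurons
#'
#' One-to-one assignment between detected components and ground-truth
#' centroids minimizing the total centroid distance, restricted to pairs
#' within `tolerance_px` (solved exactly by the Hungarian algorithm, not
#' greedily).  Ties resolve deterministically to the lowest truth id.
#'
#' @param detections a [DetectionSet-class] (or data.frame with
#'   `id`, `centroid_row`, `centroid_col`).
#' @param truth a [GroundTruth-class] (or data.frame like
#'   `neurons(truth)`).
#' @param tolerance_px maximum centroid distance for a valid pair.  The
#'   default used elsewhere in the package is 1.5 x the mean nucleus
#'   radius, so a detection sitting on the right nucleus always matches.
#' @return A [MatchResult-class].
#' @export
matchDetections <- function(detections, truth, tolerance_px) {
  stopifnot(tolerance_px > 0)
  det <- if (is(detections, "DetectionSet")) components(detections)
         else detections
  tru <- if (is(truth, "GroundTruth")) neurons(truth) else truth
  det <- det[order(det$id), , drop = FALSE]
  tru <- tru[order(tru$id), , drop = FALSE]
  nd <- nrow(det); nt <- nrow(tru)
  if (nd == 0 || nt == 0) {
    return(new("MatchResult",
               pairs = data.frame(detection_id = integer(0),
                                  truth_id = integer(0),
                                  distance_px = numeric(0)),
               unmatched_detections = as.integer(det$id),
               unmatched_truth = as.integer(tru$id),
               tolerance_px = tolerance_px))
  }
  D <- sqrt(outer(det$centroid_row, tru$centroid_row, "-")^2 +
            outer(det$centroid_col, tru$centroid_col, "-")^2)
  BIG <- 1e7
  n <- max(nd, nt)
  cost <- matrix(BIG, n, n)
  allowed <- D <= tolerance_px
  cost[seq_len(nd), seq_len(nt)] <- ifelse(allowed, D, BIG)
  assign <- .hungarian_cpp(cost)
  pairs <- data.frame(detection_id = integer(0), truth_id = integer(0),
                      distance_px = numeric(0))
  for (i in seq_len(nd)) {
    j <- assign[i]
    if (j <= nt && allowed[i, j]) {
      pairs <- rbind(pairs, data.frame(detection_id = det$id[i],
                                       truth_id = tru$id[j],
                                       distance_px = D[i, j]))
    }
  }
  new("MatchResult", pairs = pairs,
      unmatched_detections = as.integer(setdiff(det$id, pairs$detection_id)),
      unmatched_truth = as.integer(setdiff(tru$id, pairs$truth_id)),
      tolerance_px = tolerance_px)
}

#' Detection fraction: matched truths over all truths
#'
#' The proportion of ground-truth (or manually annotated) neurons that the
#' automated detection found.
#'
#' @param match a [MatchResult-class].
#' @return A fraction in [0, 1], or `NA` when there are no truths.
#' @examples
#' # 33 of 40 annotated neurons detected:
#' # detectionFraction gives 33/40 = 0.825
#' @export
detectionFraction <- function(match) {
  stopifnot(is(match, "MatchResult"))
  n_truth <- nrow(match@pairs) + length(match@unmatched_truth)
  if (n_truth == 0) return(NA_real_)
  nrow(match@pairs) / n_truth
}

#' Detection accuracy: correct detections over all detections
#'
#' A detection is correct when it matches a ground-truth neuron within
#' tolerance.
#'
#' @param match a [MatchResult-class].
#' @return A fraction in [0, 1], or `NA` when there are no detections.
#' @export
detectionAccuracy <- function(match) {
  stopifnot(is(match, "MatchResult"))
  n_det <- nrow(match@pairs) + length(match@unmatched_detections)
  if (n_det == 0) return(NA_real_)
  nrow(match@pairs) / n_det
}

#' Summary metrics of a detection-truth match
#'
#' @param match a [MatchResult-class].
#' @return A list with `detection_fraction`, `detection_accuracy`,
#'   `n_truth`, `n_detected`, `n_correct` (undefined ratios are `NA`).
#' @export
detectionMetrics <- function(match) {
  stopifnot(is(match, "MatchResult"))
  list(detection_fraction = detectionFraction(match),
       detection_accuracy = detectionAccuracy(match),
       n_truth = nrow(match@pairs) + length(match@unmatched_truth),
       n_detected = nrow(match@pairs) + length(match@unmatched_detections),
       n_correct = nrow(match@pairs))
}
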