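#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`.  A zero denominator is an error, never a silent 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return A one-row tibble `accuracy, sensitivity, specificity`.
#' @export
#' @examples
#' classification_metrics(3, 4, 2, 1)
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  total <- sum(counts)
  if (total < 1) abort("at least one observation is required")
  if (tp + fn == 0) abort("sensitivity undefined: no positive cases")
  if (tn + fp == 0) abort("specificity undefined: no negative cases")
  tibble(accuracy = (tp + tn) / total,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp))
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half — the Mann-Whitney statistic
#' normalized by `n_pos * n_neg`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels (or logical).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    abort("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Dice similarity coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.  Two empty masks are defined to agree
#' perfectly (Dice 1); empty versus non-empty is 0.
#'
#' @param st,sg binary masks ([seg_mask()] or arrays) of identical shape;
#'   conventionally the automatic segmentation and the ground truth.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(st, sg) {
  a <- if (inherits(st, "seg_mask")) st$data else st
  b <- if (inherits(sg, "seg_mask")) sg$data else sg
  if (!identical(dim(a), dim(b))) abort("masks must share a shape")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Average Euclidean distance over matched point pairs
#'
#' Points are matched under the threshold `diff` (unique nearest-neighbor
#' matching via [match_points()]); the mean pairwise distance over the `N`
#' matched pairs is returned.  `N = 0` is an error — an average over no
#' matches is undefined, not 0 or infinity.
#'
#' @param gt,pred point sets (tibbles with x, y, z or n x 3 matrices).
#' @param diff matching threshold in pixels (> 0).
#' @return Mean Euclidean distance over matched pairs.
#' @export
avg_euclidean_distance <- function(gt, pred, diff = 10) {
  if (diff <= 0) abort("diff must be > 0")
  m <- match_points(gt, pred, diff)
  if (nrow(m$pairs) == 0L)
    abort("no matched points within the threshold; average distance undefined")
  mean(m$pairs$distance)
}

#' Detection precision, recall, and F1 from match counts
#'
#' Two conventions are supported.  `"as_printed"` (the default) uses
#' precision `= NTP / NGT` and recall `= NTP / Ndetected` — note these swap
#' the conventional roles of the two denominators; `"conventional"` uses
#' precision `= NTP / Ndetected` and recall `= NTP / NGT`.  F1 is the
#' harmonic mean and is identical under either convention.
#'
#' @param n_gt number of ground-truth somata.
#' @param n_tp number of true-positive (matched) somata;
#'   `<= min(n_gt, n_detected)`.
#' @param n_detected number of detected somata.
#' @param convention `"as_printed"` or `"conventional"`.
#' @return A one-row tibble `precision, recall, f1, convention`.
#' @export
#' @examples
#' detection_metrics(10, 8, 8)                 # as-printed: P 0.8, R 1.0
#' detection_metrics(10, 8, 8, "conventional") # P 1.0, R 0.8
detection_metrics <- function(n_gt, n_tp, n_detected,
                              convention = c("as_printed", "conventional")) {
  convention <- match.arg(convention)
  if (n_tp > min(n_gt, n_detected))
    abort("n_tp cannot exceed min(n_gt, n_detected)")
  if (n_gt <= 0 || n_detected <= 0)
    abort("n_gt and n_detected must be > 0")
  if (convention == "as_printed") {
    precision <- n_tp / n_gt
    recall <- n_tp / n_detected
  } else {
    precision <- n_tp / n_detected
    recall <- n_tp / n_gt
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(precision = precision, recall = recall, f1 = f1,
         convention = convention)
}

#' Full evaluation report for a segmentation/detection result
#'
#' Bundles the segmentation and detection metrics for one predicted mask
#' against its ground truth: Dice, matched-pair average Euclidean distance,
#' and precision/recall/F1 at the matching threshold.
#'
#' @param gt_mask,pred_mask binary masks of identical shape.
#' @param gt_points,pred_points centroid point sets.
#' @param threshold matching threshold in pixels.
#' @param convention detection-metric convention (see
#'   [detection_metrics()]).
#' @return A one-row tibble with `dice`, `avg_distance`, `n_gt`,
#'   `n_detected`, `n_matched`, `precision`, `recall`, `f1`.
#' @export
evaluate_detection <- function(gt_mask, pred_mask, gt_points, pred_points,
                               threshold = 10,
                               convention = c("as_printed", "conventional")) {
  convention <- match.arg(convention)
  m <- match_points(gt_points, pred_points, threshold)
  n_matched <- nrow(m$pairs)
  dm <- detection_metrics(nrow(as_point_matrix(gt_points)), n_matched,
                          nrow(as_point_matrix(pred_points)), convention)
  tibble(dice = dice(pred_mask, gt_mask),
         avg_distance = if (n_matched > 0) mean(m$pairs$distance) else NA_real_,
         n_gt = nrow(as_point_matrix(gt_points)),
         n_detected = nrow(as_point_matrix(pred_points)),
         n_matched = n_matched,
         precision = dm$precision, recall = dm$recall, f1 = dm$f1)
}
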