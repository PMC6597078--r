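#' Intersection-over-union overlap of two boxes
#'
#' Area of overlap `area(bp n bgt) / area(bp u bgt)` under the inclusive-pixel
#' convention (a box spans `x_max - x_min + 1` rows): 0 for disjoint boxes,
#' 1 for identical boxes, symmetric in its arguments.
#'
#' @param b_p,b_gt Numeric vectors `(x_min, y_min, x_max, y_max)` with
#'   inclusive integer corners.
#' @return Overlap in `[0, 1]`.
#' @export
overlap_alpha0 <- function(b_p, b_gt) {
  .check_box(b_p)
  .check_box(b_gt)
  ix <- min(b_p[3L], b_gt[3L]) - max(b_p[1L], b_gt[1L]) + 1
  iy <- min(b_p[4L], b_gt[4L]) - max(b_p[2L], b_gt[2L]) + 1
  inter <- max(0, ix) * max(0, iy)
  a1 <- (b_p[3L] - b_p[1L] + 1) * (b_p[4L] - b_p[2L] + 1)
  a2 <- (b_gt[3L] - b_gt[1L] + 1) * (b_gt[4L] - b_gt[2L] + 1)
  inter / (a1 + a2 - inter)
}

.check_box <- function(b) {
  if (length(b) < 4L || b[3L] < b[1L] || b[4L] < b[2L]) {
    .stop_input("degenerate box: need x_min <= x_max and y_min <= y_max")
  }
  invisible(b)
}

#' Match detections to ground-truth boxes
#'
#' Greedy one-to-one matching: detections are processed in descending score
#' order and each claims the still-unmatched ground-truth box of highest
#' overlap, provided that overlap exceeds 0.5. Unclaimed detections are false
#' positives; unclaimed ground-truth boxes are false negatives.
#'
#' @param detections Data frame of positive detections with box columns and
#'   `score`.
#' @param ground_truth Data frame of ground-truth boxes (`x_min`, `y_min`,
#'   `x_max`, `y_max`).
#' @param min_overlap Matching criterion (a detection is correct when its
#'   overlap exceeds this; default 0.5).
#' @return A list of class `match_counts` with `n_tp`, `n_fp`, `n_fn` and
#'   `tp_flags` (logical per detection, in descending-score order, alongside
#'   `order` mapping back to input rows).
#' @export
match_detections <- function(detections, ground_truth, min_overlap = 0.5) {
  n_gt <- nrow(ground_truth)
  n_det <- nrow(detections)
  if (n_det == 0L) {
    return(structure(
      list(n_tp = 0L, n_fp = 0L, n_fn = n_gt,
           tp_flags = logical(0), order = integer(0)),
      class = "match_counts"
    ))
  }
  ord <- order(-detections$score, detections$x_min, detections$y_min,
               detections$x_max, detections$y_max)
  det <- detections[ord, , drop = FALSE]
  gt_free <- rep(TRUE, n_gt)
  tp <- logical(n_det)
  for (i in seq_len(n_det)) {
    if (!any(gt_free)) break
    box <- c(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i])
    iou <- .iou_one_vs_many(box, ground_truth)
    iou[!gt_free] <- -Inf
    j <- which.max(iou)
    if (iou[j] > min_overlap) {
      tp[i] <- TRUE
      gt_free[j] <- FALSE
    }
  }
  structure(
    list(
      n_tp = sum(tp), n_fp = sum(!tp), n_fn = sum(gt_free),
      tp_flags = tp, order = ord
    ),
    class = "match_counts"
  )
}

#' Precision, recall and F1 score from match counts
#'
#' `P = TP / (FP + TP)`, `R = TP / (FN + TP)`, `F1 = 2 P R / (P + R)`, with
#' 0/0 cases defined as 0.
#'
#' @param counts A `match_counts` object (or list with `n_tp`, `n_fp`,
#'   `n_fn`).
#' @return Named numeric vector `(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$n_tp
  fp <- counts$n_fp
  fn <- counts$n_fn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Miss-rate versus false-positives-per-image curve
#'
#' Sweeps a confidence threshold over the distinct detection scores; at each
#' threshold the detections scoring at least that value are matched per image
#' (greedy one-to-one, overlap > 0.5) and pooled into
#' `MR = FN / (FN + TP)` and `FPPI = FP / n_images`. Because matching is
#' greedy in score order, a detection's true/false-positive status is
#' threshold-independent and the curve is computed from cumulative counts.
#'
#' @param detections Data frame with `image_id`, box columns and `score`
#'   (all scored candidates, regardless of final label).
#' @param ground_truth Data frame with `image_id` and box columns; must be
#'   non-empty.
#' @param n_images Number of test images (FPPI denominator); defaults to the
#'   number of distinct `image_id`s in the ground truth.
#' @return A data frame of class `mr_fppi_curve` with columns `threshold`,
#'   `fppi` and `mr`, ordered by decreasing threshold.
#' @export
mr_fppi_curve <- function(detections, ground_truth,
                          n_images = length(unique(ground_truth$image_id))) {
  if (nrow(ground_truth) == 0L) .stop_input("ground truth is empty")
  if (n_images < 1L) .stop_input("need at least one test image")
  n_gt <- nrow(ground_truth)
  if (nrow(detections) == 0L) {
    out <- data.frame(threshold = Inf, fppi = 0, mr = 1)
    class(out) <- c("mr_fppi_curve", class(out))
    return(out)
  }
  ord <- order(-detections$score, detections$x_min, detections$y_min)
  det <- detections[ord, , drop = FALSE]
  tp <- logical(nrow(det))
  for (img in unique(det$image_id)) {
    di <- which(det$image_id == img)
    gt <- ground_truth[ground_truth$image_id == img, , drop = FALSE]
    if (nrow(gt) == 0L) next
    gt_free <- rep(TRUE, nrow(gt))
    for (i in di) {
      if (!any(gt_free)) break
      box <- c(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i])
      iou <- .iou_one_vs_many(box, gt)
      iou[!gt_free] <- -Inf
      j <- which.max(iou)
      if (iou[j] > 0.5) {
        tp[i] <- TRUE
        gt_free[j] <- FALSE
      }
    }
  }
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  # one curve point per distinct score: the last (lowest-ranked) detection
  # at that score
  last <- !duplicated(det$score, fromLast = TRUE)
  out <- data.frame(
    threshold = det$score[last],
    fppi = cum_fp[last] / n_images,
    mr = (n_gt - cum_tp[last]) / n_gt
  )
  class(out) <- c("mr_fppi_curve", class(out))
  out
}

#' Log-average miss rate of an MR-FPPI curve
#'
#' Samples the miss rate at nine FPPI values evenly spaced in log space over
#' `[1e-2, 1]`; for each reference value the miss rate of the largest
#' achieved FPPI not exceeding it is used (miss rate 1 when the curve has no
#' such point), and the nine samples are aggregated by geometric mean with
#' miss rates floored at 1e-10 (an arithmetic mean is available as an
#' option).
#'
#' @param curve A [mr_fppi_curve()] result (columns `fppi`, `mr`).
#' @param average `"geometric"` (default) or `"arithmetic"`.
#' @return The log-average miss rate in `[0, 1]`.
#' @export
log_average_miss_rate <- function(curve, average = c("geometric", "arithmetic")) {
  average <- match.arg(average)
  if (nrow(curve) == 0L) .stop_input("curve is empty")
  refs <- 10^seq(-2, 0, by = 0.25)
  ord <- order(curve$fppi, -curve$mr)
  fppi <- curve$fppi[ord]
  mr <- curve$mr[ord]
  samples <- vapply(refs, function(ref) {
    idx <- which(fppi <= ref)
    if (length(idx) == 0L) 1 else mr[max(idx)]
  }, numeric(1))
  samples <- pmax(samples, 1e-10)
  if (average == "geometric") exp(mean(log(samples))) else mean(samples)
}
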