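#' Intersection over union of two boxes
#'
#' Boxes are `(x, y, w, h)` in the COCO convention with continuous
#' (half-open) pixel areas `w * h`. Zero-area boxes are rejected.
#'
#' @param a,b Length-4 numeric boxes `(x, y, w, h)`, `w, h > 0`.
#' @return IoU in `[0, 1]`.
#' @examples
#' bbox_iou(c(0, 0, 2, 2), c(1, 0, 2, 2))   # 1/3
#' @export
bbox_iou <- function(a, b) {
  if (a[3] <= 0 || a[4] <= 0 || b[3] <= 0 || b[4] <= 0)
    stop_invalid("boxes must have positive width and height")
  iw <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}

# IoU of one box against a gt matrix (n x 4), vectorised
iou_vs_many <- function(a, gts) {
  if (nrow(gts) == 0) return(numeric(0))
  iw <- pmax(0, pmin(a[1] + a[3], gts[, 1] + gts[, 3]) - pmax(a[1], gts[, 1]))
  ih <- pmax(0, pmin(a[2] + a[4], gts[, 2] + gts[, 4]) - pmax(a[2], gts[, 2]))
  inter <- iw * ih
  inter / (a[3] * a[4] + gts[, 3] * gts[, 4] - inter)
}

#' Match detections to ground truth at an IoU threshold
#'
#' Standard greedy protocol: detections are visited in order of decreasing
#' confidence (ties keep input order); each detection claims the unmatched
#' ground-truth box of highest IoU at or above `iou_thr` (IoU ties go to the
#' lower ground-truth index) and becomes a true positive, otherwise it is a
#' false positive. Each ground-truth box is matched at most once.
#'
#' @param detections n x 4 matrix of boxes `(x, y, w, h)` (or a data frame
#'   with those columns).
#' @param confidences Length-n confidences in `[0, 1]`.
#' @param gts m x 4 matrix of ground-truth boxes.
#' @param iou_thr IoU threshold (default 0.5).
#' @return List with `tp` (logical per detection, in input order),
#'   `matched_gt` (gt index per detection, `NA` for FP), and `gt_matched`
#'   (logical per ground-truth box).
#' @export
match_detections <- function(detections, confidences, gts, iou_thr = 0.5) {
  det <- as.matrix(detections); gts <- as.matrix(gts)
  n <- nrow(det)
  if (length(confidences) != n)
    stop_invalid("need one confidence per detection")
  if (any(confidences < 0 | confidences > 1))
    stop_invalid("confidences must lie in [0,1]")
  ord <- order(-confidences)             # stable: ties keep input order
  tp <- logical(n); matched <- rep(NA_integer_, n)
  gt_matched <- logical(nrow(gts))
  for (i in ord) {
    ious <- iou_vs_many(det[i, ], gts)
    ious[gt_matched] <- -1
    if (length(ious) && max(ious) >= iou_thr) {
      j <- which.max(ious)               # lowest index on ties
      tp[i] <- TRUE; matched[i] <- j; gt_matched[j] <- TRUE
    }
  }
  list(tp = tp, matched_gt = matched, gt_matched = gt_matched)
}

# AP from a confidence-ranked TP/FP sequence: all-points interpolation of the
# precision envelope over recall.
ap_from_ranked <- function(tp_ranked, n_gt) {
  if (n_gt < 1) stop_undefined_metric("average precision needs >= 1 ground-truth box")
  if (length(tp_ranked) == 0) return(0)
  ctp <- cumsum(tp_ranked)
  cfp <- cumsum(!tp_ranked)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  env <- rev(cummax(rev(precision)))     # precision envelope
  sum(diff(c(0, recall)) * env)
}

#' Average precision of a set of scored detections
#'
#' Matches detections to ground truth per image at `iou_thr`, ranks all
#' detections globally by confidence (ties keep input order), and integrates
#' the all-points precision envelope over recall — the single-class
#' mAP at IoU 0.5 when `iou_thr = 0.5`.
#'
#' @param detections Data frame with columns `image_id, x, y, w, h,
#'   confidence`.
#' @param ground_truth Data frame with columns `image_id, x, y, w, h`.
#' @param iou_thr IoU threshold (default 0.5).
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(detections, ground_truth, iou_thr = 0.5) {
  evaluate_detections(detections, ground_truth, iou_thr)$ap
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2pr / (p + r)`; defined as 0 when
#' both are 0.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @examples
#' f1_score(0.9, 0.6)   # 0.72
#' @export
f1_score <- function(precision, recall) {
  if (any(c(precision, recall) < 0) || any(c(precision, recall) > 1))
    stop_invalid("precision and recall must lie in [0,1]")
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Evaluate detections against ground truth
#'
#' The full single-class evaluation: per-image greedy matching at `iou_thr`,
#' global confidence ranking, average precision (all-points interpolation),
#' the precision-recall table, and the F1 sweep over confidence thresholds
#' with its maximum (reported F1 values correspond to this max-F1 operating
#' point; the threshold attaining it is returned alongside).
#'
#' @param detections Data frame with columns `image_id, x, y, w, h,
#'   confidence`.
#' @param ground_truth Data frame with columns `image_id, x, y, w, h`.
#' @param iou_thr IoU threshold (default 0.5).
#' @return List with `ap`, `max_f1`, `max_f1_threshold`, `n_gt`, `n_det`,
#'   and `pr` — a data frame of `(confidence, tp, precision, recall, f1)`
#'   in ranked order.
#' @export
evaluate_detections <- function(detections, ground_truth, iou_thr = 0.5) {
  need_d <- c("image_id", "x", "y", "w", "h", "confidence")
  need_g <- c("image_id", "x", "y", "w", "h")
  if (!all(need_d %in% names(detections)))
    stop_invalid("detections need columns %s", paste(need_d, collapse = ", "))
  if (!all(need_g %in% names(ground_truth)))
    stop_invalid("ground_truth needs columns %s", paste(need_g, collapse = ", "))
  n_gt <- nrow(ground_truth)
  if (n_gt < 1) stop_undefined_metric("no ground-truth boxes: AP undefined")
  tp_all <- logical(nrow(detections))
  for (img in unique(detections$image_id)) {
    di <- which(detections$image_id == img)
    gi <- ground_truth$image_id == img
    m <- match_detections(as.matrix(detections[di, c("x", "y", "w", "h")]),
                          detections$confidence[di],
                          as.matrix(ground_truth[gi, c("x", "y", "w", "h")]),
                          iou_thr)
    tp_all[di] <- m$tp
  }
  ord <- order(-detections$confidence)
  tpr <- tp_all[ord]
  conf <- detections$confidence[ord]
  ap <- ap_from_ranked(tpr, n_gt)
  if (length(tpr)) {
    ctp <- cumsum(tpr)
    precision <- ctp / seq_along(tpr)
    recall <- ctp / n_gt
    f1 <- ifelse(precision + recall == 0, 0,
                 2 * precision * recall / (precision + recall))
    pr <- data.frame(confidence = conf, tp = tpr,
                     precision = precision, recall = recall, f1 = f1)
    # evaluate F1 at thresholds that keep whole confidence ties together
    keep <- !duplicated(conf, fromLast = TRUE)
    best <- which.max(f1[keep])
    max_f1 <- f1[keep][best]
    max_thr <- conf[keep][best]
  } else {
    pr <- data.frame(confidence = numeric(), tp = logical(),
                     precision = numeric(), recall = numeric(), f1 = numeric())
    max_f1 <- 0; max_thr <- NA_real_
  }
  list(ap = ap, max_f1 = max_f1, max_f1_threshold = max_thr,
       n_gt = n_gt, n_det = nrow(detections), pr = pr)
}

#' Ground truth and detections from files
#'
#' Helpers for the evaluation CLI: `coco_ground_truth()` flattens a COCO file
#' into the `(image_id, x, y, w, h)` frame [evaluate_detections()] expects;
#' `read_detections()` reads a JSON array of
#' `{image_id, bbox: [x,y,w,h], confidence}` records.
#'
#' @param path File path.
#' @return A data frame (see Details).
#' @export
coco_ground_truth <- function(path) {
  cc <- read_coco(path)
  data.frame(image_id = cc$annotations$image_id,
             x = cc$annotations$x, y = cc$annotations$y,
             w = cc$annotations$w, h = cc$annotations$h)
}

#' @rdname coco_ground_truth
#' @export
read_detections <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(recs) == 0)
    return(data.frame(image_id = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), confidence = numeric()))
  do.call(rbind, lapply(recs, function(r) {
    if (is.null(r$image_id) || is.null(r$bbox) || is.null(r$confidence))
      stop_format("detection record needs image_id, bbox, confidence")
    bb <- as.numeric(unlist(r$bbox))
    data.frame(image_id = r$image_id, x = bb[1], y = bb[2], w = bb[3],
               h = bb[4], confidence = r$confidence)
  }))
}
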