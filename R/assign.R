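# Dual-weighting label assignment: candidate bags around ground-truth
# centers, a positive weight rewarding classification/regression agreement,
# and a negative weight equal to the probability a candidate is negative
# (linear in IoU on the COCO evaluation interval) times its importance.

#' Positive sample weight
#'
#' `w_pos = t exp(mu t)` with `t = s * iou^beta`: monotone in both the
#' predicted score `s` and the IoU of the decoded box, with `mu` controlling
#' the relative gap between consistent and inconsistent candidates.
#'
#' @param s Predicted score(s) in `[0, 1]`.
#' @param iou IoU(s) of the decoded box with its ground truth.
#' @param mu Gap factor.
#' @param beta IoU balancing exponent.
#' @return Numeric weights `>= 0`.
#' @export
positive_weight <- function(s, iou, mu = 5, beta = 2) {
  t <- s * iou^beta
  t * exp(mu * t)
}

#' Negative sample weight
#'
#' The probability of being a negative sample is 1 below `iou_lo`, 0 above
#' `iou_hi`, and linear in between (the unique line through those
#' endpoints); it is multiplied by the importance `s^gamma`.
#'
#' @param s Predicted score(s) in `[0, 1]`.
#' @param iou IoU(s) with the assigned ground truth.
#' @param gamma Importance modulation factor.
#' @param iou_lo,iou_hi Interval endpoints (COCO evaluation thresholds).
#' @return Numeric weights in `[0, 1]`.
#' @export
negative_weight <- function(s, iou, gamma = 2, iou_lo = 0.5, iou_hi = 0.95) {
  p <- ifelse(iou <= iou_lo, 1,
              ifelse(iou >= iou_hi, 0, (iou_hi - iou) / (iou_hi - iou_lo)))
  p * s^gamma
}

#' Focal loss for a single binary target
#'
#' `target = 1`: `-alpha (1-s)^eta log s`; `target = 0`:
#' `-(1-alpha) s^eta log(1-s)`.
#'
#' @param s Predicted probability in (0, 1).
#' @param target 0 or 1.
#' @param alpha Class balance factor.
#' @param eta Focusing exponent.
#' @return Numeric loss values.
#' @export
focal_loss <- function(s, target, alpha = 0.25, eta = 2) {
  n <- max(length(s), length(target))
  s <- rep_len(s, n)
  target <- rep_len(target, n)
  ifelse(target == 1,
         -alpha * (1 - s)^eta * log(s),
         -(1 - alpha) * s^eta * log(1 - s))
}

#' Build candidate bags for a set of ground-truth boxes
#'
#' A location joins a ground truth's bag iff it lies inside the box, within
#' `candidate_radius * stride` (Chebyshev distance) of the box center, and
#' the location's maximum regression distance falls in its level's range.
#' Locations claimed by several ground truths go to the smallest-area one.
#'
#' @param locations Tibble from [pyramid_locations()].
#' @param gt_boxes Tibble of ground-truth corner boxes with `category_id`.
#' @param config A [detector_config()] (radius and regression ranges).
#' @return List: `assignment` (ground-truth row index per location, `NA` for
#'   non-candidates) and `bags` (list of location row indices per ground
#'   truth).
#' @export
build_candidate_bags <- function(locations, gt_boxes, config) {
  n <- nrow(locations)
  ng <- if (is.null(gt_boxes)) 0L else nrow(gt_boxes)
  if (ng == 0L)
    return(list(assignment = rep(NA_integer_, n), bags = list()))
  rr <- config$regress_ranges
  lo <- rr[locations$level]; hi <- rr[locations$level + 1L]
  assignment <- rep(NA_integer_, n)
  areas <- (gt_boxes$x_max - gt_boxes$x_min) * (gt_boxes$y_max - gt_boxes$y_min)
  best_area <- rep(Inf, n)
  for (g in seq_len(ng)) {
    gb <- gt_boxes[g, ]
    l <- locations$x - gb$x_min; r <- gb$x_max - locations$x
    t <- locations$y - gb$y_min; b <- gb$y_max - locations$y
    inside <- l > 0 & r > 0 & t > 0 & b > 0
    maxd <- pmax(l, r, t, b)
    in_range <- maxd >= lo & maxd <= hi
    cx <- (gb$x_min + gb$x_max) / 2; cy <- (gb$y_min + gb$y_max) / 2
    near <- pmax(abs(locations$x - cx), abs(locations$y - cy)) <=
      config$candidate_radius * locations$stride
    ok <- inside & in_range & near & areas[g] < best_area
    assignment[ok] <- g
    best_area[ok] <- areas[g]
  }
  bags <- lapply(seq_len(ng), function(g) which(assignment == g))
  list(assignment = assignment, bags = bags)
}

# centerness target of FCOS: sqrt(min(l,r)/max(l,r) * min(t,b)/max(t,b))
centerness_target <- function(locations, gt_boxes, assignment) {
  idx <- which(!is.na(assignment))
  out <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]; g <- assignment[i]
    gb <- gt_boxes[g, ]
    l <- locations$x[i] - gb$x_min; r <- gb$x_max - locations$x[i]
    t <- locations$y[i] - gb$y_min; b <- gb$y_max - locations$y[i]
    out[k] <- sqrt(min(l, r) / max(l, r) * min(t, b) / max(t, b))
  }
  out
}
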