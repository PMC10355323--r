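# COCO-style detection metrics: AP averaged over the IoU threshold grid
# [0.5:0.05:0.95] with 101-point interpolated precision, AR at the detection
# cap, and the small/medium/large area breakdown.

coco_area_ranges <- function() {
  list(all = c(0, Inf), small = c(0, 32^2),
       medium = c(32^2, 96^2), large = c(96^2, Inf))
}

# greedy per-image, per-class matching at one IoU threshold.
# Returns per-detection TP flag + ignore flag, and the non-ignored GT count.
match_image_class <- function(dets, gts, tau, area_range) {
  ng <- nrow(gts)
  nd <- nrow(dets)
  gt_area <- (gts$x_max - gts$x_min) * (gts$y_max - gts$y_min)
  gt_ignore <- gt_area < area_range[1] | gt_area > area_range[2]
  gt_matched <- rep(FALSE, ng)
  tp <- rep(FALSE, nd); ignore <- rep(FALSE, nd)
  if (nd) {
    iou <- if (ng) box_iou(dets, gts) else matrix(0, nd, 0)
    for (d in seq_len(nd)) {
      best <- 0; best_g <- 0L
      # prefer non-ignored ground truth; fall back to ignored
      for (pass in 1:2) {
        pool <- which(!gt_matched & (if (pass == 1) !gt_ignore else gt_ignore))
        for (g in pool) {
          if (iou[d, g] >= tau && iou[d, g] > best) {
            best <- iou[d, g]; best_g <- g
          }
        }
        if (best_g > 0L) break
      }
      if (best_g > 0L) {
        gt_matched[best_g] <- TRUE
        if (gt_ignore[best_g]) ignore[d] <- TRUE else tp[d] <- TRUE
      } else {
        da <- (dets$x_max[d] - dets$x_min[d]) * (dets$y_max[d] - dets$y_min[d])
        if (da < area_range[1] || da > area_range[2]) ignore[d] <- TRUE
      }
    }
  }
  list(tp = tp, ignore = ignore, n_gt = sum(!gt_ignore))
}

ap_from_matches <- function(scores, tp, ignore, n_gt) {
  if (n_gt == 0) return(c(ap = NA_real_, recall = NA_real_))
  keep <- !ignore
  scores <- scores[keep]; tp <- tp[keep]
  ord <- order(scores, decreasing = TRUE)
  tp <- tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  # monotone precision envelope, sampled at 101 recall points
  if (length(precision)) {
    for (i in rev(seq_along(precision))[-1])
      precision[i] <- max(precision[i], precision[i + 1])
  }
  rgrid <- seq(0, 1, 0.01)
  pr <- vapply(rgrid, function(r) {
    i <- which(recall >= r - 1e-12)
    if (length(i)) precision[i[1]] else 0
  }, numeric(1))
  c(ap = mean(pr), recall = if (length(recall)) max(recall) else 0)
}

#' Evaluate detections against ground truth, COCO style
#'
#' AP at each IoU threshold uses greedy score-descending matching (each
#' ground truth matchable once) and 101-point interpolated precision; AP is
#' the mean over thresholds `0.5:0.05:0.95`, AR the mean over thresholds of
#' the recall at the detection cap. Size bins follow the COCO area
#' conventions (small < 32^2, medium < 96^2, large otherwise); out-of-range
#' ground truth and the detections matching it are ignored, not penalized.
#' All values are percentages. With no ground truth and no detections the
#' metrics are undefined and returned as `NA`.
#'
#' @param detections Tibble with `image_id, category_id, score` and corner
#'   coordinates.
#' @param ground_truth Tibble of annotations (`image_id, category_id`,
#'   corners), e.g. `data$annotations` of a `coco_dataset`.
#' @param iou_thresholds IoU threshold grid.
#' @param max_detections Per-image, per-class detection cap.
#' @return An `eval_result` tibble with one row: `AP, AP50, AP75, AP_s,
#'   AP_m, AP_l, AR, AR_s, AR_m, AR_l`.
#' @export
evaluate_detections <- function(detections, ground_truth,
                                iou_thresholds = seq(0.5, 0.95, 0.05),
                                max_detections = 100L) {
  if ((is.null(detections) || nrow(detections) == 0) &&
      (is.null(ground_truth) || nrow(ground_truth) == 0)) {
    out <- tibble::tibble(AP = NA_real_, AP50 = NA_real_, AP75 = NA_real_,
                          AP_s = NA_real_, AP_m = NA_real_, AP_l = NA_real_,
                          AR = NA_real_, AR_s = NA_real_, AR_m = NA_real_,
                          AR_l = NA_real_)
    return(structure(out, class = c("eval_result", class(out))))
  }
  if (is.null(detections)) detections <- empty_detections()
  img_ids <- unique(c(detections$image_id, ground_truth$image_id))
  classes <- unique(c(detections$category_id, ground_truth$category_id))
  ranges <- coco_area_ranges()
  # per (range, threshold): pooled AP over classes
  cell <- function(range_name, tau) {
    rng <- ranges[[range_name]]
    aps <- c(); recalls <- c()
    for (cl in classes) {
      scores <- c(); tp <- c(); ig <- c(); n_gt <- 0
      for (im in img_ids) {
        d <- detections[detections$image_id == im &
                        detections$category_id == cl, ]
        if (nrow(d) > max_detections)
          d <- dplyr::slice_max(d, .data$score, n = max_detections,
                                with_ties = FALSE)
        g <- ground_truth[ground_truth$image_id == im &
                          ground_truth$category_id == cl, ]
        mm <- match_image_class(d[order(-d$score), ], g, tau, rng)
        scores <- c(scores, sort(d$score, decreasing = TRUE))
        tp <- c(tp, mm$tp); ig <- c(ig, mm$ignore); n_gt <- n_gt + mm$n_gt
      }
      r <- ap_from_matches(scores, tp, ig, n_gt)
      aps <- c(aps, r["ap"]); recalls <- c(recalls, r["recall"])
    }
    c(ap = mean(aps, na.rm = TRUE), recall = mean(recalls, na.rm = TRUE))
  }
  grid <- expand.grid(range = names(ranges), tau = iou_thresholds,
                      stringsAsFactors = FALSE)
  vals <- mapply(function(r, t) cell(r, t), grid$range, grid$tau)
  grid$ap <- vals["ap", ]; grid$recall <- vals["recall", ]
  m <- function(r) 100 * mean(grid$ap[grid$range == r], na.rm = FALSE)
  mr <- function(r) 100 * mean(grid$recall[grid$range == r], na.rm = FALSE)
  at <- function(r, t) 100 * grid$ap[grid$range == r & abs(grid$tau - t) < 1e-9]
  out <- tibble::tibble(
    AP = m("all"), AP50 = at("all", 0.5), AP75 = at("all", 0.75),
    AP_s = m("small"), AP_m = m("medium"), AP_l = m("large"),
    AR = mr("all"), AR_s = mr("small"), AR_m = mr("medium"), AR_l = mr("large"))
  structure(out, class = c("eval_result", class(out)))
}

#' @export
print.eval_result <- function(x, ...) {
  cat("COCO-style evaluation (percent):\n")
  NextMethod()
}

#' @rdname evaluate_detections
#' @param x,object An `eval_result`.
#' @param ... Unused.
#' @export
tidy.eval_result <- function(x, ...) {
  tibble::tibble(metric = names(x), value = unlist(x[1, ], use.names = FALSE))
}

#' @rdname evaluate_detections
#' @export
glance.eval_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname evaluate_detections
#' @export
autoplot.eval_result <- function(object, ...) {
  df <- tidy(object)
  df$group <- ifelse(grepl("^AP", df$metric), "precision", "recall")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "percent", x = NULL, title = "Detection metrics") +
    ggplot2::theme_minimal()
}
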