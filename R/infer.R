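# Inference post-processing: score threshold, per-level top-k, class-wise
# greedy NMS, and the per-image detection cap.

#' Inference configuration
#'
#' @param score_threshold Minimum fused confidence (default 0.4).
#' @param pre_nms_top_k Detections kept per pyramid level before NMS.
#' @param nms_iou IoU threshold of the greedy class-wise NMS.
#' @param max_detections Per-image cap after NMS, ranked by confidence.
#' @return An `infer_config` list.
#' @export
infer_config <- function(score_threshold = 0.4, pre_nms_top_k = 1000L,
                         nms_iou = 0.6, max_detections = 100L) {
  stopifnot(score_threshold > 0, score_threshold < 1)
  structure(list(score_threshold = score_threshold,
                 pre_nms_top_k = as.integer(pre_nms_top_k),
                 nms_iou = nms_iou,
                 max_detections = as.integer(max_detections)),
            class = "infer_config")
}

#' Greedy non-maximum suppression
#'
#' Repeatedly keeps the highest-scored box and discards boxes overlapping it
#' with IoU above `iou_threshold`.
#'
#' @param boxes Matrix or tibble of corner boxes.
#' @param scores Numeric scores.
#' @param iou_threshold Suppression threshold.
#' @return Integer indices of the surviving boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.6) {
  boxes <- as_box_matrix(boxes)
  ord <- order(scores, decreasing = TRUE)
  keep <- integer()
  while (length(ord)) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (!length(ord)) break
    ious <- box_iou_pairs(boxes[rep(i, length(ord)), , drop = FALSE],
                          boxes[ord, , drop = FALSE])
    ord <- ord[ious <= iou_threshold]
  }
  keep
}

# head outputs (numeric) -> detections tibble
postprocess_detections <- function(m, outs, locations, cfg_infer,
                                   width, height) {
  num <- collect_head_numeric(m, outs, locations, width, height)
  ncls <- m$config$n_classes
  per_level <- list()
  for (l in seq_along(outs)) {
    rows <- which(locations$level == l)
    cand <- list()
    for (cl in seq_len(ncls)) {
      s <- num$cls_prob[rows, cl] * num$ctr_prob[rows]
      ok <- which(s >= cfg_infer$score_threshold)
      if (!length(ok)) next
      cand[[cl]] <- tibble::tibble(row = rows[ok], category_id = cl,
                                   score = s[ok])
    }
    cand <- dplyr::bind_rows(cand)
    if (!nrow(cand)) next
    cand <- dplyr::slice_max(cand, .data$score, n = cfg_infer$pre_nms_top_k,
                             with_ties = FALSE)
    per_level[[l]] <- cand
  }
  pooled <- dplyr::bind_rows(per_level)
  if (!nrow(pooled)) return(empty_detections())
  boxes <- num$boxes[pooled$row, ]
  out <- dplyr::bind_cols(pooled["category_id"], pooled["score"], boxes)
  kept <- dplyr::bind_rows(lapply(split(out, out$category_id), function(df) {
    df[nms(df, df$score, cfg_infer$nms_iou), ]
  }))
  dplyr::slice_max(kept, .data$score, n = cfg_infer$max_detections,
                   with_ties = FALSE)
}

empty_detections <- function() {
  tibble::tibble(category_id = integer(), score = double(),
                 x_min = double(), y_min = double(),
                 x_max = double(), y_max = double())
}

#' Detect objects in one image
#'
#' Runs the full forward pass (no gradients recorded) and the standard
#' post-processing chain: per-level confidence threshold and top-k, class-wise
#' NMS, per-image detection cap. Scores are the fused class-times-centerness
#' confidence. Box coordinates are mapped back to the input image scale.
#'
#' @param model A trained `fcos_lsc_model`.
#' @param image H x W x 3 array in `[0, 1]`.
#' @param cfg An [infer_config()].
#' @param target_size Optional `c(width, height)` resize before inference.
#' @return Tibble of detections: `category_id, score`, corner coordinates.
#' @export
detect <- function(model, image, cfg = infer_config(), target_size = NULL) {
  ts <- target_size %||% c(dim(image)[2], dim(image)[1])
  pp <- preprocess_sample(list(image = image, boxes = NULL),
                          train_mode = FALSE, target_size = ts)
  dets <- with_no_grad({
    outs <- detector_forward(model, ad_const(pp$image))
    locs <- pyramid_locations(attr(outs, "level_shapes"), model$config$strides)
    postprocess_detections(model, outs, locs, cfg,
                           pp$size["width"], pp$size["height"])
  })
  # undo the resize so boxes live on the caller's image
  sx <- pp$ops$resize["sx"]; sy <- pp$ops$resize["sy"]
  dets$x_min <- dets$x_min / sx; dets$x_max <- dets$x_max / sx
  dets$y_min <- dets$y_min / sy; dets$y_max <- dets$y_max / sy
  dets
}

#' Run detection over a dataset
#'
#' @param model A trained model.
#' @param data A `coco_dataset`.
#' @param cfg An [infer_config()].
#' @param target_size Optional resize applied to every image.
#' @return Tibble of detections with an `image_id` column (COCO results
#'   layout once written with [write_detections()]).
#' @export
detect_dataset <- function(model, data, cfg = infer_config(),
                           target_size = NULL) {
  purrr::map_dfr(data$images$image_id, function(id) {
    sm <- load_sample(data, id)
    d <- detect(model, sm$image, cfg, target_size)
    if (nrow(d)) d$image_id <- id else d$image_id <- integer()
    d
  })
}

#' Write detections as a COCO results JSON list
#'
#' @param detections Tibble from [detect_dataset()].
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_detections <- function(detections, path) {
  res <- lapply(seq_len(nrow(detections)), function(i) {
    r <- detections[i, ]
    list(image_id = r$image_id, category_id = r$category_id,
         bbox = c(r$x_min, r$y_min, r$x_max - r$x_min, r$y_max - r$y_min),
         score = r$score)
  })
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
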