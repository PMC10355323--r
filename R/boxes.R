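# Axis-aligned boxes as continuous 0-based corner coordinates with
# exclusive-edge semantics: area = (x_max - x_min) * (y_max - y_min).
# COCO [x, y, w, h] appears only at the serialization boundary.

#' Pairwise and cross intersection-over-union of corner boxes
#'
#' Boxes are matrices (or data frames) with columns `x_min, y_min, x_max,
#' y_max` in continuous 0-based corner coordinates.
#'
#' @param a,b Box matrices; `box_iou()` returns the `nrow(a)` by `nrow(b)`
#'   cross-IoU matrix.
#' @return A numeric matrix of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  x1 <- outer(a[, 1], b[, 1], pmax); y1 <- outer(a[, 2], b[, 2], pmax)
  x2 <- outer(a[, 3], b[, 3], pmin); y2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  un <- outer(area_a, area_b, `+`) - inter
  iou <- inter / un
  iou[un <= 0] <- 0
  iou
}

as_box_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x_min", "y_min", "x_max", "y_max")])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  x
}

# rowwise IoU of aligned box pairs
box_iou_pairs <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  x1 <- pmax(a[, 1], b[, 1]); y1 <- pmax(a[, 2], b[, 2])
  x2 <- pmin(a[, 3], b[, 3]); y2 <- pmin(a[, 4], b[, 4])
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  un <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
        (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter
  ifelse(un > 0, inter / un, 0)
}

#' Generalized IoU loss between two boxes
#'
#' `1 - GIoU(b, b')` where `GIoU = IoU - (|C| - |union|) / |C|` and `C` is the
#' smallest enclosing axis-aligned box. The loss lies in `[0, 2]`; it is 0
#' exactly when the boxes coincide, and for nested boxes it reduces to
#' `1 - IoU`.
#'
#' @param a,b Boxes as length-4 vectors or aligned matrices
#'   (`x_min, y_min, x_max, y_max`).
#' @return Numeric vector of losses.
#' @export
giou_loss <- function(a, b) {
  a <- as_box_matrix(a); b <- as_box_matrix(b)
  area_a <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  area_b <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  if (any(area_a <= 0) || any(area_b <= 0))
    stop("giou_loss: degenerate (zero-area) box")
  x1 <- pmax(a[, 1], b[, 1]); y1 <- pmax(a[, 2], b[, 2])
  x2 <- pmin(a[, 3], b[, 3]); y2 <- pmin(a[, 4], b[, 4])
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  un <- area_a + area_b - inter
  cx1 <- pmin(a[, 1], b[, 1]); cy1 <- pmin(a[, 2], b[, 2])
  cx2 <- pmax(a[, 3], b[, 3]); cy2 <- pmax(a[, 4], b[, 4])
  enc <- (cx2 - cx1) * (cy2 - cy1)
  giou <- inter / un - (enc - un) / enc
  1 - giou
}

# mirror boxes horizontally inside an image of given width
flip_boxes <- function(boxes, width) {
  out <- boxes
  out$x_min <- width - boxes$x_max
  out$x_max <- width - boxes$x_min
  out
}

clip_boxes <- function(boxes, width, height) {
  boxes$x_min <- pmin(pmax(boxes$x_min, 0), width)
  boxes$x_max <- pmin(pmax(boxes$x_max, 0), width)
  boxes$y_min <- pmin(pmax(boxes$y_min, 0), height)
  boxes$y_max <- pmin(pmax(boxes$y_max, 0), height)
  boxes
}

coco_to_corners <- function(x, y, w, h) {
  tibble::tibble(x_min = x, y_min = y, x_max = x + w, y_max = y + h)
}

corners_to_coco <- function(boxes) {
  cbind(boxes$x_min, boxes$y_min,
        boxes$x_max - boxes$x_min, boxes$y_max - boxes$y_min)
}
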