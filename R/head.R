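# Decoupled dense prediction head, shared across pyramid levels: a
# classification tower and a parallel regression tower; the regression tower
# carries both the 4-distance box branch and the center-offset branch
# (the two tasks share that tower's parameters). Box distances go through
# exp() times a learnable per-level scale.

define_head <- function(m) {
  cfg <- m$config
  fc <- cfg$fpn_channels
  for (i in seq_len(cfg$head_convs)) {
    def_conv(m, sprintf("head.cls%d", i), 3L, fc, fc, bias = FALSE)
    def_gn(m, sprintf("head.cls%d.gn", i), fc)
    def_conv(m, sprintf("head.reg%d", i), 3L, fc, fc, bias = FALSE)
    def_gn(m, sprintf("head.reg%d.gn", i), fc)
  }
  cls_bias <- -log((1 - cfg$prior_prob) / cfg$prior_prob)
  def_conv(m, "head.cls_pred", 3L, fc, cfg$n_classes, bias_init = cls_bias)
  def_conv(m, "head.reg_pred", 3L, fc, 4L)
  def_conv(m, "head.ctr_pred", 3L, fc, 1L)
  for (l in seq_along(cfg$strides))
    def_scalar(m, sprintf("head.scale%d", l), cfg$scale_init)
  invisible(NULL)
}

# pyramid -> per level list(cls (H,W,ncls), reg_raw (H,W,4), ctr (H,W,1))
head_forward <- function(m, pyr) {
  cfg <- m$config
  lapply(seq_along(pyr), function(l) {
    f <- pyr[[l]]
    hc <- f; hr <- f
    for (i in seq_len(cfg$head_convs)) {
      hc <- apply_conv_gn_relu(m, sprintf("head.cls%d", i),
                               sprintf("head.cls%d.gn", i), hc)
      hr <- apply_conv_gn_relu(m, sprintf("head.reg%d", i),
                               sprintf("head.reg%d.gn", i), hr)
    }
    cls <- apply_conv(m, "head.cls_pred", hc)
    reg <- apply_conv(m, "head.reg_pred", hr)
    ctr <- apply_conv(m, "head.ctr_pred", hr)
    if (is_shp(f)) return(list(cls = cls, reg = reg, ctr = ctr))
    scale <- p_(m, sprintf("head.scale%d", l))
    list(cls = cls, reg = reg, ctr = ctr, scale = scale)
  })
}

# full forward pass: padded image array -> head outputs + level shapes
detector_forward <- function(m, x) {
  stages <- extract_stages(m, x)
  pyr <- build_pyramid(m, stages)
  if (m$config$use_lsc) pyr <- lsc_stack(m, pyr)
  outs <- head_forward(m, pyr)
  attr(outs, "level_shapes") <- lapply(pyr, shape_of)
  outs
}

#' Pyramid location anchor points
#'
#' Each feature-map cell at `(row, col)` (0-based) on a level of stride `s`
#' maps to the image-plane point `(s (col + 0.5), s (row + 0.5))`.
#'
#' @param level_shapes List of per-level `(h, w)` shapes.
#' @param strides Integer vector of level strides.
#' @return Tibble with `level, row, col, x, y, stride`.
#' @export
pyramid_locations <- function(level_shapes, strides) {
  purrr::map_dfr(seq_along(level_shapes), function(l) {
    h <- level_shapes[[l]]$h; w <- level_shapes[[l]]$w
    s <- strides[l]
    tidyr::expand_grid(col = seq_len(w) - 1L, row = seq_len(h) - 1L) |>
      dplyr::mutate(level = l, x = s * (.data$col + 0.5),
                    y = s * (.data$row + 0.5), stride = s) |>
      dplyr::select("level", "row", "col", "x", "y", "stride")
  })
}

# decode (l, t, r, b) distances at given locations into corner boxes,
# clipped to the image
decode_boxes <- function(locations, deltas, width, height) {
  b <- tibble::tibble(
    x_min = locations$x - deltas[, 1], y_min = locations$y - deltas[, 2],
    x_max = locations$x + deltas[, 3], y_max = locations$y + deltas[, 4])
  clip_boxes(b, width, height)
}

# numeric (no-gradient) view of the head outputs at every location, aligned
# with pyramid_locations() row order
collect_head_numeric <- function(m, outs, locations, width, height) {
  cfg <- m$config
  n <- nrow(locations)
  ncls <- cfg$n_classes
  cls_p <- matrix(0, n, ncls); ctr_p <- numeric(n); deltas <- matrix(0, n, 4)
  offset <- 0L
  for (l in seq_along(outs)) {
    o <- outs[[l]]
    d <- dim(o$cls$value)
    np <- d[1] * d[2]
    rows <- offset + seq_len(np)
    cm <- matrix(o$cls$value, np, ncls)
    cls_p[rows, ] <- 1 / (1 + exp(-cm))
    ctr_p[rows] <- 1 / (1 + exp(-as.numeric(o$ctr$value)))
    sc <- o$scale$value
    dm <- matrix(o$reg$value, np, 4)
    deltas[rows, ] <- exp(pmin(dm, 12)) * sc
    offset <- offset + np
  }
  # location tibble is ordered level, then col-major over (row, col): match
  # the array memory order (row fastest) used above
  boxes <- decode_boxes(locations, deltas, width, height)
  list(cls_prob = cls_p, ctr_prob = ctr_p, deltas = deltas, boxes = boxes)
}
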