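# Composite detection loss on the autodiff graph.
#
# Dual-weighting mode: over bag members, -w_pos log s - w_neg log(1 - s)
# plus focal loss against 0 over non-candidates; regression is w_pos-weighted
# GIoU loss. Both weights are recomputed from the current predictions every
# iteration but carry no gradient themselves (they act as supervision
# strengths); the per-image sum is normalized by sum(w_pos) clamped at 1.
#
# Plain-FCOS mode: focal loss with target 1 on positives / 0 elsewhere,
# binary cross-entropy on the centerness target, and centerness-weighted
# GIoU regression, normalized by the positive count.

LOG_EPS <- 1e-6

# gather AD quantities for bag members, level by level
gather_members <- function(m, outs, locations, cand, assignment, gt_boxes) {
  cfg <- m$config
  ncls <- cfg$n_classes
  lv <- locations$level[cand]
  offset <- 0L
  parts <- list()
  for (l in seq_along(outs)) {
    d <- dim(outs[[l]]$cls$value)
    np <- d[1] * d[2]
    sel <- which(lv == l)
    if (length(sel)) {
      i_global <- cand[sel]
      loc_flat <- i_global - offset
      cat_id <- gt_boxes$category_id[assignment[i_global]]
      o <- outs[[l]]
      cls_l <- ad_gather(o$cls, loc_flat + np * (cat_id - 1L))
      ctr_l <- ad_gather(o$ctr, loc_flat)
      reg <- lapply(1:4, function(k)
        ad_mul(ad_exp(ad_clamp(ad_gather(o$reg, loc_flat + np * (k - 1L)),
                               -50, 12)), o$scale))
      parts[[length(parts) + 1L]] <-
        list(sel = sel, cls = cls_l, ctr = ctr_l, reg = reg)
    }
    offset <- offset + np
  }
  if (!length(parts)) return(NULL)
  ord <- unlist(lapply(parts, `[[`, "sel"))
  g <- list(
    cls_logit = ad_cat(lapply(parts, `[[`, "cls")),
    ctr_logit = ad_cat(lapply(parts, `[[`, "ctr")),
    deltas = lapply(1:4, function(k)
      ad_cat(lapply(parts, function(p) p$reg[[k]])))
  )
  g$order <- ord  # permutation mapping concat order -> seq_along(cand)
  g
}

ad_giou_loss <- function(x_min, y_min, x_max, y_max, gt) {
  ix1 <- ad_pmax2(x_min, gt[, 1]); iy1 <- ad_pmax2(y_min, gt[, 2])
  ix2 <- ad_pmin2(x_max, gt[, 3]); iy2 <- ad_pmin2(y_max, gt[, 4])
  inter <- ad_mul(ad_relu(ad_sub(ix2, ix1)), ad_relu(ad_sub(iy2, iy1)))
  area_p <- ad_mul(ad_sub(x_max, x_min), ad_sub(y_max, y_min))
  area_g <- (gt[, 3] - gt[, 1]) * (gt[, 4] - gt[, 2])
  un <- ad_sub(ad_add(area_p, area_g), inter)
  ex1 <- ad_pmin2(x_min, gt[, 1]); ey1 <- ad_pmin2(y_min, gt[, 2])
  ex2 <- ad_pmax2(x_max, gt[, 3]); ey2 <- ad_pmax2(y_max, gt[, 4])
  enc <- ad_mul(ad_sub(ex2, ex1), ad_sub(ey2, ey1))
  giou <- ad_sub(ad_div(inter, un), ad_div(ad_sub(enc, un), enc))
  ad_sub(1, giou)
}

# focal-against-zero over masked entries of a probability array node
ad_focal_neg_sum <- function(s_arr, mask, alpha, eta) {
  s <- ad_clamp(s_arr, LOG_EPS, 1 - LOG_EPS)
  term <- ad_mul(ad_pow(s, eta), ad_neg(ad_log(ad_sub(1, s))))
  ad_sum(term, mask * (1 - alpha))
}

# fused probability array for one level (class prob x center prob)
level_fused_prob <- function(o, ncls) {
  s_cls <- ad_sigmoid(o$cls)
  s_ctr <- ad_sigmoid(o$ctr)
  if (ncls == 1L) return(ad_mul(s_cls, s_ctr))
  d <- dim(o$cls$value)
  np <- d[1] * d[2]
  rep_ctr <- ad_reshape(ad_gather(s_ctr, rep(seq_len(np), ncls)), d)
  ad_mul(s_cls, rep_ctr)
}

#' Detection loss for one image
#'
#' Runs label assignment on the current predictions and assembles the
#' classification + regression loss on the autodiff graph.
#'
#' @param m Model.
#' @param outs Output of `detector_forward()`.
#' @param locations Tibble from [pyramid_locations()] for these outputs.
#' @param gt_boxes Tibble of ground-truth boxes (`category_id`, corners);
#'   may be empty.
#' @param width,height Unpadded image size in pixels.
#' @return List with the scalar loss `node` and a one-row `log` tibble
#'   (total, positive, negative and regression components, counts).
#' @noRd
detection_loss <- function(m, outs, locations, gt_boxes, width, height,
                           iteration = Inf) {
  cfg <- m$config
  # static-assigner warm-up: dual weights are functions of the predictions
  # and carry no signal at random initialization
  assigner <- if (cfg$assigner == "dual_weight" &&
                  iteration < (cfg$assign_warmup_iters %||% 0L))
    "fcos" else cfg$assigner
  ncls <- cfg$n_classes
  bags <- build_candidate_bags(locations, gt_boxes, cfg)
  cand <- which(!is.na(bags$assignment))

  # non-candidate focal mask per level (all class channels of non-candidates)
  noncand_masks <- list()
  offset <- 0L
  for (l in seq_along(outs)) {
    d <- dim(outs[[l]]$cls$value)
    np <- d[1] * d[2]
    mask <- matrix(1, np, ncls)
    lc <- cand[locations$level[cand] == l]
    if (length(lc)) mask[lc - offset, ] <- 0
    noncand_masks[[l]] <- array(mask, d)
    offset <- offset + np
  }

  fused_mode <- cfg$score_mode == "fused"
  zero <- ad_const(0)

  if (assigner == "dual_weight") {
    focal_terms <- lapply(seq_along(outs), function(l) {
      s_arr <- if (fused_mode) level_fused_prob(outs[[l]], ncls)
               else ad_sigmoid(outs[[l]]$cls)
      ad_focal_neg_sum(s_arr, noncand_masks[[l]], cfg$focal_alpha, cfg$focal_eta)
    })
    l_focal <- Reduce(ad_add, focal_terms)
    if (length(cand)) {
      g <- gather_members(m, outs, locations, cand, bags$assignment, gt_boxes)
      ord <- g$order
      s_cls <- ad_sigmoid(g$cls_logit)
      s_node <- if (fused_mode) ad_mul(s_cls, ad_sigmoid(g$ctr_logit)) else s_cls
      s_node <- ad_clamp(s_node, LOG_EPS, 1 - LOG_EPS)
      xs <- locations$x[cand][ord]; ys <- locations$y[cand][ord]
      x_min <- ad_sub(xs, g$deltas[[1]]); y_min <- ad_sub(ys, g$deltas[[2]])
      x_max <- ad_add(xs, g$deltas[[3]]); y_max <- ad_add(ys, g$deltas[[4]])
      gt <- as_box_matrix(gt_boxes[bags$assignment[cand][ord], ])
      giou <- ad_giou_loss(x_min, y_min, x_max, y_max, gt)
      # detached weights from the same (unclipped) quantities
      s_num <- s_node$value
      pb <- cbind(x_min$value, y_min$value, x_max$value, y_max$value)
      iou_num <- box_iou_pairs(pb, gt)
      w_pos <- positive_weight(s_num, iou_num, cfg$mu, cfg$beta)
      w_neg <- negative_weight(s_num, iou_num, cfg$gamma, cfg$iou_lo, cfg$iou_hi)
      l_pos <- ad_sum(ad_neg(ad_log(s_node)), w_pos)
      l_negw <- ad_sum(ad_neg(ad_log(ad_sub(1, s_node))), w_neg)
      z <- max(sum(w_pos), 1)
      l_reg <- ad_sum(giou, w_pos)
    } else {
      l_pos <- zero; l_negw <- zero; l_reg <- zero
      z <- 1; w_pos <- numeric()
    }
    # weighted bag terms are normalized by the weight mass; the background
    # focal sum by the candidate count, as in the baseline - dividing it by
    # sum(w_pos) would switch off background suppression as the weights grow
    zf <- max(length(cand), 1)
    l_neg_n <- ad_add(ad_mul(l_negw, 1 / z), ad_mul(l_focal, 1 / zf))
    total <- ad_add(ad_add(ad_mul(l_pos, 1 / z), l_neg_n),
                    ad_mul(l_reg, cfg$lambda / z))
    log <- tibble::tibble(
      loss_total = total$value,
      loss_pos = l_pos$value / z,
      loss_neg = l_neg_n$value,
      loss_reg = l_reg$value / z,
      n_pos = length(cand), sum_wpos = sum(w_pos))
    return(list(node = total, log = log))
  }

  # plain-FCOS assignment/loss
  focal_terms <- lapply(seq_along(outs), function(l)
    ad_focal_neg_sum(ad_sigmoid(outs[[l]]$cls), noncand_masks[[l]],
                     cfg$focal_alpha, cfg$focal_eta))
  l_focal <- Reduce(ad_add, focal_terms)
  n_pos <- length(cand)
  if (n_pos) {
    g <- gather_members(m, outs, locations, cand, bags$assignment, gt_boxes)
    ord <- g$order
    s_cls <- ad_clamp(ad_sigmoid(g$cls_logit), LOG_EPS, 1 - LOG_EPS)
    one_m <- ad_sub(1, s_cls)
    l_pos <- ad_sum(ad_mul(ad_pow(one_m, cfg$focal_eta),
                           ad_neg(ad_log(s_cls))), rep(cfg$focal_alpha, n_pos))
    ctr_t <- centerness_target(locations, gt_boxes, bags$assignment)[ord]
    s_ctr <- ad_clamp(ad_sigmoid(g$ctr_logit), LOG_EPS, 1 - LOG_EPS)
    l_ctr <- ad_add(ad_sum(ad_neg(ad_log(s_ctr)), ctr_t),
                    ad_sum(ad_neg(ad_log(ad_sub(1, s_ctr))), 1 - ctr_t))
    xs <- locations$x[cand][ord]; ys <- locations$y[cand][ord]
    x_min <- ad_sub(xs, g$deltas[[1]]); y_min <- ad_sub(ys, g$deltas[[2]])
    x_max <- ad_add(xs, g$deltas[[3]]); y_max <- ad_add(ys, g$deltas[[4]])
    gt <- as_box_matrix(gt_boxes[bags$assignment[cand][ord], ])
    giou <- ad_giou_loss(x_min, y_min, x_max, y_max, gt)
    l_reg <- ad_mul(ad_sum(giou, ctr_t), 1 / max(sum(ctr_t), LOG_EPS))
    z <- max(n_pos, 1)
    total <- ad_add(ad_mul(ad_add(ad_add(l_pos, l_focal), l_ctr), 1 / z),
                    ad_mul(l_reg, cfg$lambda))
    log <- tibble::tibble(
      loss_total = total$value,
      loss_pos = (l_pos$value + l_ctr$value) / z,
      loss_neg = l_focal$value / z,
      loss_reg = l_reg$value,
      n_pos = n_pos, sum_wpos = NA_real_)
  } else {
    total <- l_focal
    log <- tibble::tibble(loss_total = total$value, loss_pos = 0,
                          loss_neg = total$value, loss_reg = 0,
                          n_pos = 0, sum_wpos = NA_real_)
  }
  list(node = total, log = log)
}
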