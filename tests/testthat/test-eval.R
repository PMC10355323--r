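# NMS against a brute-force oracle and the COCO-style evaluator against
# worked examples plus an independently coded reference implementation.

# O(n^2) reference NMS written independently of the package implementation
brute_nms <- function(boxes, scores, thr) {
  n <- nrow(boxes)
  alive <- rep(TRUE, n)
  keep <- integer()
  repeat {
    cand <- which(alive)
    if (!length(cand)) break
    i <- cand[which.max(scores[cand])]
    keep <- c(keep, i)
    alive[i] <- FALSE
    for (j in which(alive)) {
      if (as.numeric(box_iou(boxes[i, , drop = FALSE],
                             boxes[j, , drop = FALSE])) > thr)
        alive[j] <- FALSE
    }
  }
  keep
}

test_that("greedy NMS keeps the right survivors", {
  b <- rbind(c(0, 0, 10, 10), c(0, 0, 10, 10), c(20, 20, 30, 30))
  colnames(b) <- c("x_min", "y_min", "x_max", "y_max")
  keep <- nms(b, c(0.9, 0.8, 0.7), 0.6)
  expect_equal(keep, c(1, 3))
  # disjoint boxes all survive
  b2 <- cbind(x_min = seq(0, 90, 10), y_min = 0,
              x_max = seq(5, 95, 10), y_max = 5)
  expect_length(nms(b2, runif(10), 0.5), 10)
})

test_that("NMS equals the brute-force oracle on random instances", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(2:15, 1)
    x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
    b <- cbind(x_min = x0, y_min = y0,
               x_max = x0 + runif(n, 5, 40), y_max = y0 + runif(n, 5, 40))
    s <- runif(n)
    thr <- runif(1, 0.2, 0.8)
    expect_equal(nms(b, s, thr), brute_nms(b, s, thr))
  }
})

test_that("evaluator reproduces the single-detection worked example", {
  # one GT, one detection with IoU 0.6: AP50 = 100, AP75 = 0,
  # AP = mean over the 10 thresholds of [tau <= 0.6] = 30.0
  gt <- tibble::tibble(image_id = 1L, category_id = 1L,
                       x_min = 0, y_min = 0, x_max = 10, y_max = 10)
  # a box shifted 2.5 px: intersection 7.5x10, union 12.5x10 -> IoU 0.6
  det <- tibble::tibble(image_id = 1L, category_id = 1L, score = 0.9,
                        x_min = 2.5, y_min = 0, x_max = 12.5, y_max = 10)
  iou <- as.numeric(box_iou(det[, 4:7], gt[, 3:6]))
  expect_equal(iou, 0.6)
  ev <- evaluate_detections(det, gt)
  expect_equal(ev$AP50, 100)
  expect_equal(ev$AP75, 0)
  expect_equal(ev$AP, 30)
  # detection matching nothing
  det0 <- det; det0$x_min <- 50; det0$x_max <- 60
  expect_equal(evaluate_detections(det0, gt)$AP, 0)
})

test_that("perfect detections score 100 everywhere defined", {
  set.seed(4)
  gt <- tibble::tibble(image_id = rep(1:3, each = 2), category_id = 1L,
                       x_min = runif(6, 0, 50), y_min = runif(6, 0, 50))
  gt$x_max <- gt$x_min + runif(6, 20, 60)
  gt$y_max <- gt$y_min + runif(6, 20, 60)
  det <- dplyr::mutate(gt, score = runif(6, 0.5, 1))
  ev <- evaluate_detections(det, gt)
  expect_equal(ev$AP, 100)
  expect_equal(ev$AR, 100)
  expect_true(ev$AP <= ev$AP50)
})

test_that("empty ground truth and detections give undefined, not zero", {
  ev <- evaluate_detections(NULL, NULL)
  expect_true(is.na(ev$AP))
  expect_true(is.na(ev$AR))
})

# An independent reference implementation of mean AP over the IoU grid,
# deliberately structured differently (per-threshold loops, explicit
# 101-point interpolation, no ignore logic - exercised only on datasets
# where every ground truth is in range).
reference_map <- function(det, gt, taus = seq(0.5, 0.95, 0.05)) {
  aps <- numeric(0)
  for (tau in taus) {
    rows <- list()
    for (im in unique(c(det$image_id, gt$image_id))) {
      d <- det[det$image_id == im, ]
      d <- d[order(-d$score), ]
      g <- gt[gt$image_id == im, ]
      used <- rep(FALSE, nrow(g))
      for (k in seq_len(nrow(d))) {
        ious <- if (nrow(g)) as.numeric(box_iou(d[k, ], g)) else numeric()
        ious[used] <- -1
        j <- if (length(ious)) which.max(ious) else 0L
        hit <- length(ious) > 0 && ious[j] >= tau
        if (hit) used[j] <- TRUE
        rows[[length(rows) + 1]] <- c(score = d$score[k], tp = as.numeric(hit))
      }
    }
    n_gt <- nrow(gt)
    if (!length(rows)) { aps <- c(aps, 0); next }
    m <- do.call(rbind, rows)
    m <- m[order(-m[, "score"]), , drop = FALSE]
    tp <- cumsum(m[, "tp"]); fp <- cumsum(1 - m[, "tp"])
    rec <- tp / n_gt; prec <- tp / (tp + fp)
    ap <- 0
    for (r in seq(0, 1, 0.01)) {
      p <- prec[rec >= r - 1e-12]
      ap <- ap + (if (length(p)) max(p) else 0) / 101
    }
    aps <- c(aps, ap)
  }
  100 * mean(aps)
}

test_that("evaluator agrees with the independent reference on random sets", {
  set.seed(77)
  for (rep in 1:10) {
    n_img <- sample(2:4, 1)
    gt <- purrr::map_dfr(seq_len(n_img), function(im) {
      n <- sample(1:4, 1)
      x0 <- runif(n, 0, 60); y0 <- runif(n, 0, 60)
      tibble::tibble(image_id = im, category_id = 1L, x_min = x0, y_min = y0,
                     x_max = x0 + runif(n, 33, 60),  # all "medium/large": no
                     y_max = y0 + runif(n, 33, 60))  # ignore logic triggered
    })
    det <- purrr::map_dfr(seq_len(n_img), function(im) {
      base <- gt[gt$image_id == im, ]
      n <- nrow(base)
      jit <- function(v) v + rnorm(n, 0, 6)
      d <- tibble::tibble(image_id = im, category_id = 1L,
                          score = runif(n),
                          x_min = jit(base$x_min), y_min = jit(base$y_min),
                          x_max = jit(base$x_max), y_max = jit(base$y_max))
      d$x_max <- pmax(d$x_max, d$x_min + 1)
      d$y_max <- pmax(d$y_max, d$y_min + 1)
      d
    })
    ours <- evaluate_detections(det, gt)$AP
    ref <- reference_map(det, gt)
    expect_equal(ours, ref, tolerance = 1e-4)
  }
})
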