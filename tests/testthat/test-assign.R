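# Dual-weighting functions and candidate-bag construction.

test_that("positive weight follows t*exp(mu*t) and is monotone", {
  expect_equal(positive_weight(0, 0.8), 0)
  expect_equal(positive_weight(0.7, 0), 0)
  expect_equal(positive_weight(1, 1, mu = 5, beta = 2), exp(5))
  expect_equal(round(positive_weight(1, 1, mu = 5, beta = 2), 3), 148.413)
  for (mu in c(1, 5)) {
    for (beta in c(1, 2)) {
      w1 <- positive_weight(0.9, 0.9, mu, beta)
      w2 <- positive_weight(0.5, 0.9, mu, beta)
      w3 <- positive_weight(0.5, 0.5, mu, beta)
      expect_gt(w1, w2); expect_gt(w2, w3)
    }
  }
  # non-decreasing on a grid in both arguments
  g <- seq(0, 1, 0.1)
  for (iou in g) expect_true(all(diff(positive_weight(g, iou)) >= 0))
  for (s in g) expect_true(all(diff(positive_weight(s, g)) >= 0))
})

test_that("negative probability is 1 below, 0 above, linear between", {
  # endpoint continuity forced by the interval [0.5, 0.95]
  expect_equal(negative_weight(1, 0.5), 1)
  expect_equal(negative_weight(1, 0.95), 0)
  expect_equal(negative_weight(1, 0.725), 0.5)   # midpoint
  expect_equal(negative_weight(0.5, 0.3, gamma = 2), 0.25)
  expect_equal(negative_weight(0.9, 0.96), 0)
  # the linear segment is -k*iou + b with k = 20/9, b = 19/9
  iou <- 0.8
  expect_equal(negative_weight(1, iou), -20 / 9 * iou + 19 / 9)
  # continuity and monotonicity on a fine grid
  g <- seq(0, 1, 0.005)
  p <- negative_weight(1, g)
  expect_true(all(diff(p) <= 1e-12))
  expect_lt(max(abs(diff(p))), 0.02)  # no jumps at the seams
  # same w_pos, different IoU -> different w_neg (finer supervision signal)
  s1 <- 0.6; iou1 <- 0.6
  t1 <- s1 * iou1^2
  iou2 <- 0.8; s2 <- t1 / iou2^2     # engineered equal w_pos
  expect_equal(positive_weight(s1, iou1), positive_weight(s2, iou2))
  expect_false(isTRUE(all.equal(negative_weight(s1, iou1),
                                negative_weight(s2, iou2))))
})

test_that("focal loss matches direct evaluation", {
  expect_equal(focal_loss(0.5, 0, alpha = 0.25, eta = 2),
               -0.75 * 0.25 * log(0.5))
  expect_equal(round(focal_loss(0.5, 0, 0.25, 2), 4), 0.13)
  # eta = 0 reduces to alpha-scaled cross-entropy
  s <- c(0.2, 0.7)
  expect_equal(focal_loss(s, 1, 0.5, 0), -0.5 * log(s))
  expect_equal(focal_loss(s, 0, 0.5, 0), -0.5 * log(1 - s))
  # well-classified negative vanishes
  expect_lt(focal_loss(1e-6, 0, 0.25, 2), 1e-11)
})

test_that("candidate bags match a brute-force enumeration of the rule", {
  cfg <- detector_config(candidate_radius = 1.5)
  # toy 16x16 image: only levels whose stride fits produce locations
  shapes <- list(list(h = 2, w = 2), list(h = 1, w = 1))
  locs <- pyramid_locations(shapes, strides = c(8L, 16L))
  cfg$strides <- c(8L, 16L)
  cfg$regress_ranges <- c(0, 64, Inf)
  gt <- tibble::tibble(x_min = 0, y_min = 0, x_max = 16, y_max = 16,
                       category_id = 1L)
  got <- build_candidate_bags(locs, gt, cfg)
  # independent brute force over every location
  brute <- vapply(seq_len(nrow(locs)), function(i) {
    x <- locs$x[i]; y <- locs$y[i]; s <- locs$stride[i]
    l <- x - gt$x_min; r <- gt$x_max - x; t <- y - gt$y_min; b <- gt$y_max - y
    inside <- min(l, r, t, b) > 0
    rr <- cfg$regress_ranges[c(locs$level[i], locs$level[i] + 1)]
    in_range <- max(l, r, t, b) >= rr[1] && max(l, r, t, b) <= rr[2]
    near <- max(abs(x - 8), abs(y - 8)) <= 1.5 * s
    inside && in_range && near
  }, logical(1))
  expect_equal(!is.na(got$assignment), brute)
  expect_gt(sum(brute), 0)

  # nested ground truths sharing a center: shared members go to the smaller
  gt2 <- tibble::tibble(x_min = c(0, 4), y_min = c(0, 4),
                        x_max = c(16, 12), y_max = c(16, 12),
                        category_id = 1L)
  got2 <- build_candidate_bags(locs, gt2, cfg)
  shared <- which(!is.na(got2$assignment))
  expect_true(all(got2$assignment[shared] == 2 |
                  !(locs$x[shared] > 4 & locs$x[shared] < 12 &
                    locs$y[shared] > 4 & locs$y[shared] < 12)))

  # no ground truth: everything is a non-candidate
  got0 <- build_candidate_bags(locs, gt[0, ], cfg)
  expect_true(all(is.na(got0$assignment)))
  expect_length(got0$bags, 0)
})

test_that("bag members respect radius and containment on random scenes", {
  cfg <- detector_config()
  shapes <- list(list(h = 16, w = 16), list(h = 8, w = 8), list(h = 4, w = 4),
                 list(h = 2, w = 2), list(h = 1, w = 1))
  locs <- pyramid_locations(shapes, cfg$strides)
  set.seed(8)
  for (rep in 1:5) {
    n <- sample(1:4, 1)
    x0 <- runif(n, 0, 90); y0 <- runif(n, 0, 90)
    gt <- tibble::tibble(x_min = x0, y_min = y0,
                         x_max = x0 + runif(n, 10, 38),
                         y_max = y0 + runif(n, 10, 38),
                         category_id = 1L)
    got <- build_candidate_bags(locs, gt, cfg)
    for (g in seq_len(n)) {
      for (i in got$bags[[g]]) {
        expect_true(locs$x[i] > gt$x_min[g] && locs$x[i] < gt$x_max[g])
        cx <- (gt$x_min[g] + gt$x_max[g]) / 2
        cy <- (gt$y_min[g] + gt$y_max[g]) / 2
        expect_lte(max(abs(locs$x[i] - cx), abs(locs$y[i] - cy)),
                   cfg$candidate_radius * locs$stride[i])
      }
    }
  }
})
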