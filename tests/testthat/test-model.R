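# Architecture contracts: stage strides, pyramid sizes, attention
# identities, head decoding and parameter sharing.

test_that("backbone stages follow the stride table and DCN degenerates", {
  cfg <- tiny_model_config()
  m <- build_detector(cfg, seed = 4)
  x <- ns$ad_const(array(rnorm(96 * 64 * 3), c(64, 96, 3)))
  st <- ns$with_no_grad(ns$extract_stages(m, x))
  expect_equal(dim(st$C2$value)[1:2], c(16, 24))   # stride 4
  expect_equal(dim(st$C3$value)[1:2], c(8, 12))    # stride 8
  expect_equal(dim(st$C4$value)[1:2], c(4, 6))     # stride 16
  expect_equal(dim(st$C5$value)[1:2], c(2, 3))     # stride 32
  expect_equal(dim(st$C5$value)[3], cfg$stage_out_widths[4])

  # zero-initialized offset branches: DCN model == plain model with the
  # same weights (modulation starts at sigmoid(12) ~ 1)
  plain <- build_detector(detector_config(width_mult = 0.25,
                                          fpn_channels = 32L,
                                          use_dcn = FALSE, use_lsc = FALSE,
                                          assigner = "fcos"), seed = 4)
  for (nm in plain$param_names)
    if (!startsWith(nm, "lsc.")) plain$params[[nm]]$value <- m$params[[nm]]$value
  st2 <- ns$with_no_grad(ns$extract_stages(plain, x))
  expect_equal(st$C5$value, st2$C5$value, tolerance = 1e-3)
})

test_that("pyramid sizes follow the ceil-division chain at 608x416", {
  cfg <- tiny_model_config()
  # symbolic pass is enough for shapes and costs nothing
  sk <- ns$build_skeleton(cfg)
  outs <- ns$detector_forward(sk, ns$shp(416, 608, 3))
  shp <- attr(outs, "level_shapes")
  got <- lapply(shp, function(s) c(s$w, s$h))
  expect_equal(got, list(c(76, 52), c(38, 26), c(19, 13), c(10, 7), c(5, 4)))
})

test_that("top-down fusion adds the lateral to the upsampled upper level", {
  cfg <- tiny_model_config()
  m <- build_detector(cfg, seed = 6)
  x <- ns$ad_const(array(rnorm(64 * 64 * 3), c(64, 64, 3)))
  st <- ns$with_no_grad(ns$extract_stages(m, x))
  pyr <- ns$with_no_grad(ns$build_pyramid(m, st))
  # force the C5 lateral to zero: F4 must equal conv_out(lateral(C4))
  m$params[["fpn.lat5.w"]]$value[] <- 0
  m$params[["fpn.lat5.b"]]$value[] <- 0
  pyr0 <- ns$with_no_grad(ns$build_pyramid(m, st))
  lat4 <- ns$with_no_grad(ns$apply_conv(m, "fpn.lat4", st$C4))
  ref <- ns$with_no_grad(ns$apply_conv(m, "fpn.out4", lat4))
  expect_equal(pyr0[[2]]$value, ref$value, tolerance = 1e-12)
  expect_equal(max(abs(pyr0[[3]]$value)), 0)  # F5 itself is zero
  expect_false(isTRUE(all.equal(pyr[[2]]$value, pyr0[[2]]$value)))
})

test_that("scale attention is a hard-sigmoid scalar per level", {
  cfg <- tiny_model_config()
  m <- build_detector(cfg, seed = 7)
  lvl <- ns$ad_const(array(rnorm(8 * 8 * 32), c(8, 8, 32)))
  # zeroed branch weights: hs(relu(0)) = 0.5, output = X / 2
  m$params[["lsc.b1.scale.w"]]$value[] <- 0
  m$params[["lsc.b1.scale.b"]]$value[] <- 0
  out <- ns$with_no_grad(ns$scale_attention(m, "lsc.b1", list(lvl)))
  expect_equal(out[[1]]$value, lvl$value / 2, tolerance = 1e-12)
  # saturated pre-activation >= +3 leaves the level unchanged
  m$params[["lsc.b1.scale.b"]]$value[] <- 5
  out2 <- ns$with_no_grad(ns$scale_attention(m, "lsc.b1", list(lvl)))
  expect_equal(out2[[1]]$value, lvl$value, tolerance = 1e-12)
  # hand-evaluated composition on a constant level
  const <- ns$ad_const(array(2, c(4, 4, 32)))
  w <- rnorm(32) * 0.1
  m$params[["lsc.b1.scale.w"]]$value[] <- w
  m$params[["lsc.b1.scale.b"]]$value[] <- 0.3
  out3 <- ns$with_no_grad(ns$scale_attention(m, "lsc.b1", list(const)))
  pre <- sum(2 * w) + 0.3
  hs <- min(max((max(pre, 0) + 3) / 6, 0), 1)
  expect_equal(out3[[1]]$value[1, 1, 1], 2 * hs, tolerance = 1e-12)
})

test_that("spatial attention averages deformable views of the neighbors", {
  cfg <- detector_config(width_mult = 0.25, fpn_channels = 2L,
                         lsc_blocks = 1L, lsc_reduction = 1L)
  m <- build_detector(cfg, seed = 8)
  # identity delta kernels, zero offsets (already zero-init), modulation ~ 1
  for (pos in c("low", "mid", "high")) {
    w <- array(0, c(3, 3, 2, 2))
    w[2, 2, 1, 1] <- 1; w[2, 2, 2, 2] <- 1
    m$params[[paste0("lsc.b1.sp_", pos, ".w")]]$value <- w
  }
  f1 <- ns$ad_const(array(rnorm(4 * 4 * 2), c(4, 4, 2)))
  f2 <- ns$ad_const(array(rnorm(2 * 2 * 2), c(2, 2, 2)))
  out <- ns$with_no_grad(ns$spatial_attention(m, "lsc.b1", list(f1, f2)))
  up <- ns$with_no_grad(ns$apply_resize(f2, 4, 4))
  expect_equal(out[[1]]$value, (f1$value + up$value) / 2, tolerance = 1e-4)
  down <- ns$with_no_grad(ns$apply_resize(f1, 2, 2))
  expect_equal(out[[2]]$value, (f2$value + down$value) / 2, tolerance = 1e-4)
})

test_that("channel attention starts as ReLU and evaluates the max form", {
  # base coefficients (a1, a2, b1, b2) = (1, 0, 0, 0): operator is max(x, 0)
  cfg <- tiny_model_config()
  m <- build_detector(cfg, seed = 9)
  lvl <- ns$ad_const(array(rnorm(4 * 4 * 32), c(4, 4, 32)))
  out <- ns$with_no_grad(ns$channel_attention(m, "lsc.b1", list(lvl)))
  expect_equal(out[[1]]$value, pmax(lvl$value, 0), tolerance = 1e-12)
  # direct evaluation of the dynamic form: a1=1,b1=0,a2=0.1,b2=0 at x=-2
  dr <- ns$ad_dyn_relu(ns$ad_const(array(-2, c(1, 1, 1))),
                       ns$ad_const(1), ns$ad_const(0),
                       ns$ad_const(0.1), ns$ad_const(0))
  expect_equal(as.numeric(dr$value), -0.2)
  # a1 = a2 = 1, b = 0 is the identity
  dr2 <- ns$ad_dyn_relu(lvl, ns$ad_const(rep(1, 32)), ns$ad_const(rep(0, 32)),
                        ns$ad_const(rep(1, 32)), ns$ad_const(rep(0, 32)))
  expect_equal(dr2$value, lvl$value)
})

test_that("attention stack preserves shapes and respects block count", {
  cfg <- detector_config(width_mult = 0.25, fpn_channels = 32L,
                         lsc_blocks = 2L)
  m <- build_detector(cfg, seed = 10)
  sizes <- list(c(8, 6), c(4, 3), c(2, 2), c(1, 1), c(1, 1))
  pyr <- lapply(sizes, function(s)
    ns$ad_const(array(rnorm(s[1] * s[2] * 32), c(s[1], s[2], 32))))
  out <- ns$with_no_grad(ns$lsc_stack(m, pyr))
  for (l in 1:5) expect_equal(dim(out[[l]]$value), dim(pyr[[l]]$value))
  # n_blocks = 2 equals manual double application
  manual <- pyr
  for (k in 1:2) {
    nm <- sprintf("lsc.b%d", k)
    manual <- ns$with_no_grad(
      ns$channel_attention(m, nm,
        ns$spatial_attention(m, nm,
          ns$scale_attention(m, nm, manual))))
  }
  for (l in 1:5)
    expect_equal(out[[l]]$value, manual[[l]]$value, tolerance = 1e-12)
})

test_that("head decodes distances around the anchor and fuses scores", {
  locs <- tibble::tibble(x = 100, y = 100)
  b <- ns$decode_boxes(locs, matrix(c(10, 20, 30, 40), 1), 1000, 1000)
  expect_equal(unlist(b), c(x_min = 90, y_min = 80, x_max = 130, y_max = 140))
  # clipping to the image
  b2 <- ns$decode_boxes(tibble::tibble(x = 4, y = 4),
                        matrix(c(10, 10, 10, 10), 1), 100, 100)
  expect_equal(unlist(b2), c(x_min = 0, y_min = 0, x_max = 14, y_max = 14))
  # score fusion is the product of the two probabilities
  expect_equal(0.8 * 0.5, 0.4)
  cfg <- tiny_model_config()
  m <- build_detector(cfg, seed = 11)
  # zero final cls weights with bias beta0: all probabilities sigmoid(beta0)
  m$params[["head.cls_pred.w"]]$value[] <- 0
  m$params[["head.cls_pred.b"]]$value[] <- 0.7
  x <- ns$ad_const(array(rnorm(64 * 64 * 3), c(64, 64, 3)))
  outs <- ns$with_no_grad(ns$detector_forward(m, x))
  locs <- pyramid_locations(attr(outs, "level_shapes"), cfg$strides)
  num <- ns$collect_head_numeric(m, outs, locs, 64, 64)
  expect_equal(unique(as.numeric(round(num$cls_prob, 10))),
               round(1 / (1 + exp(-0.7)), 10))
  # determinism: same input twice gives identical outputs
  outs2 <- ns$with_no_grad(ns$detector_forward(m, x))
  num2 <- ns$collect_head_numeric(m, outs2, locs, 64, 64)
  expect_identical(num$boxes, num2$boxes)
  # decoded boxes contain their anchor point
  expect_true(all(num$boxes$x_min <= locs$x & num$boxes$x_max >= locs$x))
  expect_true(all(num$boxes$y_min <= locs$y & num$boxes$y_max >= locs$y))
})

test_that("head parameters are shared across levels", {
  cfg <- tiny_model_config()
  m <- build_detector(cfg, seed = 12)
  # identical feature maps fed at two levels produce identical predictions
  # up to the per-level scale on the deltas
  f <- ns$ad_const(array(rnorm(4 * 4 * 32), c(4, 4, 32)))
  outs <- ns$with_no_grad(ns$head_forward(m, list(f, f, f, f, f)))
  expect_equal(outs[[1]]$cls$value, outs[[3]]$cls$value)
  expect_equal(outs[[2]]$ctr$value, outs[[5]]$ctr$value)
  expect_equal(outs[[1]]$reg$value, outs[[4]]$reg$value)
})
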