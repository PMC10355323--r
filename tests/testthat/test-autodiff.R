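# Gradient correctness of the autodiff engine against central finite
# differences, and the degenerate-case identities of the deformable kernel.

test_that("conv2d gradients match finite differences", {
  set.seed(1)
  x <- array(rnorm(7 * 6 * 3), c(7, 6, 3))
  w <- array(rnorm(3 * 3 * 3 * 4) * 0.3, c(3, 3, 3, 4))
  b <- rnorm(4)
  wts <- NULL
  loss <- function(xv, wv, bv) {
    out <- ns$cpp_conv2d(xv, wv, bv, 2L, 1L)
    if (is.null(wts)) wts <<- array(rnorm(length(out)), dim(out))
    sum(out * wts)
  }
  base <- loss(x, w, b)
  px <- ns$ad_param(x); pw <- ns$ad_param(w); pb <- ns$ad_param(b)
  node <- ns$ad_sum(ns$ad_conv2d(px, pw, pb, 2L, 1L), wts)
  ns$ad_backward(node)
  idx <- sample(length(x), 10)
  expect_equal(px$grad[idx], fd_grad(function(v) loss(v, w, b), x, idx),
               tolerance = 1e-6)
  idx <- sample(length(w), 10)
  expect_equal(pw$grad[idx], fd_grad(function(v) loss(x, v, b), w, idx),
               tolerance = 1e-6)
  expect_equal(pb$grad, fd_grad(function(v) loss(x, w, v), b, 1:4),
               tolerance = 1e-6)
})

test_that("deformable conv reduces to plain conv and obeys its gradients", {
  set.seed(2)
  x <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  w <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
  b <- rnorm(3)
  # zero offsets + unit modulation = standard convolution, exactly
  off0 <- array(0, c(6, 6, 18)); mod1 <- array(1, c(6, 6, 9))
  expect_equal(ns$cpp_deform_conv(x, w, b, off0, mod1, 1L, 1L),
               ns$cpp_conv2d(x, w, b, 1L, 1L), tolerance = 1e-12)
  # zero modulation kills the output regardless of weights
  mod0 <- array(0, c(6, 6, 9))
  out0 <- ns$cpp_deform_conv(x, w, rep(0, 3), off0, mod0, 1L, 1L)
  expect_equal(max(abs(out0)), 0)
  # gradient check on all five inputs
  off <- array(rnorm(6 * 6 * 18) * 0.6, c(6, 6, 18))
  mod <- array(runif(6 * 6 * 9), c(6, 6, 9))
  wts <- array(rnorm(6 * 6 * 3), c(6, 6, 3))
  loss <- function(xv, wv, bv, ov, mv)
    sum(ns$cpp_deform_conv(xv, wv, bv, ov, mv, 1L, 1L) * wts)
  px <- ns$ad_param(x); pw <- ns$ad_param(w); pb <- ns$ad_param(b)
  po <- ns$ad_param(off); pm <- ns$ad_param(mod)
  node <- ns$ad_sum(ns$ad_deform_conv(px, pw, pb, po, pm, 1L, 1L), wts)
  ns$ad_backward(node)
  idx <- sample(length(off), 12)
  expect_equal(po$grad[idx],
               fd_grad(function(v) loss(x, w, b, v, mod), off, idx),
               tolerance = 1e-5)
  idx <- sample(length(mod), 8)
  expect_equal(pm$grad[idx],
               fd_grad(function(v) loss(x, w, b, off, v), mod, idx),
               tolerance = 1e-5)
  idx <- sample(length(x), 8)
  expect_equal(px$grad[idx],
               fd_grad(function(v) loss(v, w, b, off, mod), x, idx),
               tolerance = 1e-5)
})

test_that("bilinear sampling at a half-pixel offset averages neighbors", {
  # 5x5 horizontal ramp, identity 1-point kernel shifted by (0, 0.5):
  # the sampled value is the mean of the two horizontally adjacent pixels
  ramp <- array(rep(1:5, each = 5), c(5, 5, 1))  # value = column index
  w <- array(0, c(3, 3, 1, 1)); w[2, 2, 1, 1] <- 1
  off <- array(0, c(5, 5, 18))
  off[, , 10] <- 0.5  # center point n = 4 (0-based), x-offset channel 2n+1
  mod <- array(1, c(5, 5, 9))
  out <- ns$cpp_deform_conv(ramp, w, numeric(0), off, mod, 1L, 1L)
  # interior columns: average of col and col+1
  expect_equal(out[3, 2, 1], (2 + 3) / 2)
  expect_equal(out[3, 4, 1], (4 + 5) / 2)
})

test_that("group norm, resize, dynamic relu gradients are exact", {
  set.seed(3)
  x <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  gamma <- runif(8, 0.5, 1.5); beta <- rnorm(8)
  wts <- array(rnorm(4 * 3 * 8), c(4, 3, 8))
  gn_loss <- function(xv, gv, bv)
    sum(ns$cpp_group_norm(xv, gv, bv, 2L, 1e-5)$value * wts)
  px <- ns$ad_param(x); pg <- ns$ad_param(gamma); pb <- ns$ad_param(beta)
  node <- ns$ad_sum(ns$ad_group_norm(px, pg, pb, 2L), wts)
  ns$ad_backward(node)
  idx <- sample(length(x), 10)
  expect_equal(px$grad[idx], fd_grad(function(v) gn_loss(v, gamma, beta), x, idx),
               tolerance = 1e-5)
  expect_equal(pg$grad, fd_grad(function(v) gn_loss(x, v, beta), gamma, 1:8),
               tolerance = 1e-5)
  expect_equal(pb$grad, fd_grad(function(v) gn_loss(x, gamma, v), beta, 1:8),
               tolerance = 1e-5)

  rz_wts <- array(rnorm(9 * 7 * 8), c(9, 7, 8))
  rz_loss <- function(xv) sum(ns$cpp_resize_bilinear(xv, 9L, 7L) * rz_wts)
  px <- ns$ad_param(x)
  ns$ad_backward(ns$ad_sum(ns$ad_resize(px, 9, 7), rz_wts))
  idx <- sample(length(x), 10)
  expect_equal(px$grad[idx], fd_grad(rz_loss, x, idx), tolerance = 1e-5)

  a1 <- runif(8, 0.5, 1.5); b1 <- rnorm(8) * 0.1
  a2 <- runif(8, -0.2, 0.4); b2 <- rnorm(8) * 0.1
  dr_loss <- function(xv) {
    np <- 12
    e <- function(v) rep(v, each = np)
    sum(pmax(xv * e(a1) + e(b1), xv * e(a2) + e(b2)) * wts)
  }
  px <- ns$ad_param(x)
  node <- ns$ad_sum(ns$ad_dyn_relu(px, ns$ad_const(a1), ns$ad_const(b1),
                                   ns$ad_const(a2), ns$ad_const(b2)), wts)
  ns$ad_backward(node)
  idx <- sample(length(x), 10)
  expect_equal(px$grad[idx], fd_grad(dr_loss, x, idx), tolerance = 1e-5)
})

test_that("gradients accumulate correctly through shared nodes", {
  # y = x used twice: dy/dx must sum both paths
  x <- ns$ad_param(c(2, 3))
  y <- ns$ad_add(ns$ad_mul(x, x), x)   # x^2 + x -> grad 2x + 1
  ns$ad_backward(ns$ad_sum(y))
  expect_equal(as.numeric(x$grad), 2 * c(2, 3) + 1)
})
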