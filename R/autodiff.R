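# Minimal reverse-mode autodiff over R arrays. A node is an environment with
# the current value, an accumulated gradient, its parents and a backward
# closure mapping the output gradient to one gradient per parent. Graphs are
# built define-by-run at every forward pass; backward() releases nothing, the
# whole tape is garbage-collected with the root.

.ad_state <- new.env(parent = emptyenv())
.ad_state$counter <- 0

new_ad_node <- function(value, parents = list(), backward = NULL,
                        requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  .ad_state$counter <- .ad_state$counter + 1
  e$id <- .ad_state$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  class(e) <- "ad_node"
  e
}

#' @noRd
ad_param <- function(value) new_ad_node(value, requires_grad = TRUE)
ad_const <- function(value) new_ad_node(value)

is_ad <- function(x) inherits(x, "ad_node")
ad_value <- function(x) if (is_ad(x)) x$value else x
as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

ad_op <- function(value, parents, backward) {
  keep <- !isTRUE(.ad_state$no_grad) &&
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  new_ad_node(value, parents = if (keep) parents else list(),
              backward = if (keep) backward else NULL)
}

# evaluate expr without recording the tape (inference mode)
with_no_grad <- function(expr) {
  old <- isTRUE(.ad_state$no_grad)
  .ad_state$no_grad <- TRUE
  on.exit(.ad_state$no_grad <- old)
  expr
}

acc_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

# Reverse topological order by iterative DFS, then one backward sweep.
ad_backward <- function(root, grad = NULL) {
  if (is.null(grad)) {
    grad <- if (is.null(dim(root$value))) rep(1, length(root$value))
            else array(1, dim = dim(root$value))
  }
  root$grad <- grad
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, i = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    n <- top$node
    if (top$i < length(n$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      child <- n$parents[[top$i + 1L]]
      key <- as.character(child$id)
      if (child$requires_grad && is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        stack[[length(stack) + 1L]] <- list(node = child, i = 0L)
      }
    } else {
      order[[length(order) + 1L]] <- n
      stack[[length(stack)]] <- NULL
    }
  }
  for (n in rev(order)) {
    if (is.null(n$backward) || is.null(n$grad)) next
    gs <- n$backward(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (p$requires_grad && !is.null(gs[[k]])) acc_grad(p, gs[[k]])
    }
    if (length(n$parents)) n$grad <- NULL  # free intermediate grads
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- elementwise ------------------------------------------------------------

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_op(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_op(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_op(av * bv, list(a, b), function(g) {
    ga <- g * bv; gb <- g * av
    if (length(av) == 1 && length(bv) > 1) ga <- sum(ga)
    if (length(bv) == 1 && length(av) > 1) gb <- sum(gb)
    list(ga, gb)
  })
}

ad_neg <- function(a) ad_op(-a$value, list(a), function(g) list(-g))

ad_relu <- function(a) {
  m <- a$value > 0
  ad_op(a$value * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_exp <- function(a) {
  v <- exp(a$value)
  ad_op(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  v <- a$value
  ad_op(log(v), list(a), function(g) list(g / v))
}

# clamp passes gradient only strictly inside the interval
ad_clamp <- function(a, lo, hi) {
  v <- pmin(pmax(a$value, lo), hi)
  inside <- a$value > lo & a$value < hi
  ad_op(v, list(a), function(g) list(g * inside))
}

# hard sigmoid: clamp((x + offset) / divisor, 0, 1)
ad_hard_sigmoid <- function(a, offset = 3, divisor = 6) {
  pre <- (a$value + offset) / divisor
  v <- pmin(pmax(pre, 0), 1)
  inside <- pre > 0 & pre < 1
  ad_op(v, list(a), function(g) list(g * inside / divisor))
}

ad_pow <- function(a, p) {
  v <- a$value^p
  ad_op(v, list(a), function(g) list(g * p * a$value^(p - 1)))
}

ad_pmax2 <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  m <- a$value >= b$value
  ad_op(pmax(a$value, b$value), list(a, b),
        function(g) list(g * m, g * (!m)))
}

ad_pmin2 <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  m <- a$value <= b$value
  ad_op(pmin(a$value, b$value), list(a, b),
        function(g) list(g * m, g * (!m)))
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_op(av / bv, list(a, b), function(g) {
    ga <- g / bv; gb <- -g * av / bv^2
    if (length(bv) == 1 && length(av) > 1) gb <- sum(gb)
    list(ga, gb)
  })
}

# ---- reductions / indexing --------------------------------------------------

ad_sum <- function(a, weights = NULL) {
  if (is.null(weights)) {
    ad_op(sum(a$value), list(a),
          function(g) list(array(g, dim = dim(a$value) %||% length(a$value))))
  } else {
    ad_op(sum(a$value * weights), list(a), function(g) list(g * weights))
  }
}

ad_gather <- function(a, idx) {
  dims <- dim(a$value) %||% length(a$value)
  ad_op(a$value[idx], list(a), function(g) {
    ga <- array(0, dim = dims)
    if (!anyDuplicated(idx)) {
      ga[idx] <- g
    } else {
      for (k in seq_along(idx)) ga[idx[k]] <- ga[idx[k]] + g[k]
    }
    list(ga)
  })
}

# elementwise mean over a list of same-shape nodes
ad_list_mean <- function(nodes) {
  n <- length(nodes)
  v <- Reduce(`+`, lapply(nodes, function(x) x$value)) / n
  ad_op(v, nodes, function(g) rep(list(g / n), n))
}

# concatenate vector nodes
ad_cat <- function(nodes) {
  lens <- vapply(nodes, function(x) length(x$value), integer(1))
  v <- unlist(lapply(nodes, function(x) x$value), use.names = FALSE)
  ends <- cumsum(lens); starts <- ends - lens + 1L
  ad_op(v, nodes, function(g)
    lapply(seq_along(nodes), function(k) g[starts[k]:ends[k]]))
}

# ---- tensor ops (compiled kernels) -----------------------------------------

ad_conv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  bias <- if (is.null(b)) numeric(0) else b$value
  if (isTRUE(.ad_state$no_grad) || !(x$requires_grad || w$requires_grad)) {
    v <- cpp_conv2d(x$value, w$value, bias, as.integer(stride), as.integer(pad))
    parents <- if (is.null(b)) list(x, w) else list(x, w, b)
    return(ad_op(v, parents, NULL))
  }
  fw <- cpp_conv2d_ws(x$value, w$value, bias, as.integer(stride), as.integer(pad))
  xd <- dim(x$value)
  need_gx <- x$requires_grad
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_op(fw$value, parents, function(g) {
    r <- cpp_conv2d_backward_ws(fw$ws, xd, w$value, g, as.integer(stride),
                                as.integer(pad), !is.null(b), need_gx)
    gx <- if (need_gx) r$gx else NULL
    if (is.null(b)) list(gx, r$gw) else list(gx, r$gw, r$gb)
  })
}

ad_deform_conv <- function(x, w, b = NULL, offsets, modulation,
                           stride = 1L, pad = 0L) {
  bias <- if (is.null(b)) numeric(0) else b$value
  v <- cpp_deform_conv(x$value, w$value, bias, offsets$value, modulation$value,
                       as.integer(stride), as.integer(pad))
  parents <- if (is.null(b)) list(x, w, offsets, modulation)
             else list(x, w, b, offsets, modulation)
  ad_op(v, parents, function(g) {
    r <- cpp_deform_conv_backward(x$value, w$value, offsets$value,
                                  modulation$value, g, as.integer(stride),
                                  as.integer(pad), !is.null(b))
    if (is.null(b)) list(r$gx, r$gw, r$goff, r$gmod)
    else list(r$gx, r$gw, r$gb, r$goff, r$gmod)
  })
}

ad_resize <- function(x, h, w) {
  d <- dim(x$value)
  if (d[1] == h && d[2] == w) return(x)
  v <- cpp_resize_bilinear(x$value, as.integer(h), as.integer(w))
  ad_op(v, list(x), function(g)
    list(cpp_resize_bilinear_backward(g, d[1], d[2])))
}

ad_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- cpp_maxpool(x$value, as.integer(k), as.integer(stride), as.integer(pad))
  d <- dim(x$value)
  ad_op(r$value, list(x), function(g)
    list(cpp_maxpool_backward(g, r$argmax, d[1], d[2])))
}

# fused conv -> group norm -> (optional) ReLU: one graph node instead of
# three, chaining the compiled backward kernels directly
ad_conv_gn_relu <- function(x, w, gamma, beta, stride = 1L, pad = 0L,
                            groups = 32L, relu = TRUE, eps = 1e-5) {
  if (isTRUE(.ad_state$no_grad) || !(x$requires_grad || w$requires_grad)) {
    cv <- cpp_conv2d(x$value, w$value, numeric(0), as.integer(stride),
                     as.integer(pad))
    gn <- cpp_group_norm(cv, gamma$value, beta$value, as.integer(groups), eps)
    v <- if (relu) gn$value * (gn$value > 0) else gn$value
    return(ad_op(v, list(x, w, gamma, beta), NULL))
  }
  fw <- cpp_conv2d_ws(x$value, w$value, numeric(0), as.integer(stride),
                      as.integer(pad))
  gn <- cpp_group_norm(fw$value, gamma$value, beta$value,
                       as.integer(groups), eps)
  mask <- if (relu) gn$value > 0 else NULL
  v <- if (relu) gn$value * mask else gn$value
  xd <- dim(x$value)
  need_gx <- x$requires_grad
  ad_op(v, list(x, w, gamma, beta), function(g) {
    if (relu) g <- g * mask
    r1 <- cpp_group_norm_backward(gn$xhat, gn$sd, gamma$value, g,
                                  as.integer(groups))
    r2 <- cpp_conv2d_backward_ws(fw$ws, xd, w$value, r1$gx,
                                 as.integer(stride), as.integer(pad),
                                 FALSE, need_gx)
    list(if (need_gx) r2$gx else NULL, r2$gw, r1$ggamma, r1$gbeta)
  })
}

# fused group norm -> ReLU (used after deformable convolutions)
ad_gn_relu <- function(x, gamma, beta, groups, relu = TRUE, eps = 1e-5) {
  gn <- cpp_group_norm(x$value, gamma$value, beta$value,
                       as.integer(groups), eps)
  mask <- if (relu) gn$value > 0 else NULL
  v <- if (relu) gn$value * mask else gn$value
  ad_op(v, list(x, gamma, beta), function(g) {
    if (relu) g <- g * mask
    r <- cpp_group_norm_backward(gn$xhat, gn$sd, gamma$value, g,
                                 as.integer(groups))
    list(r$gx, r$ggamma, r$gbeta)
  })
}

# group normalization over (H, W, channels-within-group)
ad_group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$value)
  stopifnot(d[3] %% groups == 0)
  fw <- cpp_group_norm(x$value, gamma$value, beta$value, as.integer(groups), eps)
  ad_op(fw$value, list(x, gamma, beta), function(gr) {
    r <- cpp_group_norm_backward(fw$xhat, fw$sd, gamma$value, gr,
                                 as.integer(groups))
    list(r$gx, r$ggamma, r$gbeta)
  })
}

# global average pool over H, W -> length-C vector
ad_gap <- function(x) {
  d <- dim(x$value)
  v <- colMeans(matrix(x$value, d[1] * d[2], d[3]))
  ad_op(v, list(x), function(g) {
    ga <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    list(ga)
  })
}

ad_linear <- function(x, w, b = NULL) {
  v <- as.numeric(x$value %*% w$value)
  if (!is.null(b)) v <- v + b$value
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ad_op(v, parents, function(g) {
    gx <- as.numeric(w$value %*% g)
    gw <- outer(as.numeric(x$value), g)
    if (is.null(b)) list(gx, gw) else list(gx, gw, g)
  })
}

# multiply a (H,W,C) map by a length-C channel vector
ad_channel_mul <- function(x, s) {
  d <- dim(x$value)
  sv <- s$value
  v <- x$value * rep(sv, each = d[1] * d[2])
  ad_op(v, list(x, s), function(g) {
    gx <- g * rep(sv, each = d[1] * d[2])
    gs <- colSums(matrix(g * x$value, d[1] * d[2], d[3]))
    list(gx, gs)
  })
}

# dynamic piecewise-linear activation: max(a1*x + b1, a2*x + b2),
# coefficients are length-C vectors broadcast over space
ad_dyn_relu <- function(x, a1, b1, a2, b2) {
  d <- dim(x$value)
  np <- d[1] * d[2]
  e <- function(v) rep(v, each = np)
  y1 <- x$value * e(a1$value) + e(b1$value)
  y2 <- x$value * e(a2$value) + e(b2$value)
  m <- y1 >= y2
  ad_op(pmax(y1, y2), list(x, a1, b1, a2, b2), function(g) {
    g1 <- g * m; g2 <- g * (!m)
    gx <- g1 * e(a1$value) + g2 * e(a2$value)
    csum <- function(z) colSums(matrix(z, np, d[3]))
    list(gx, csum(g1 * x$value), csum(g1), csum(g2 * x$value), csum(g2))
  })
}
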