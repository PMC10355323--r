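# Feature pyramid (F3-F7, one width everywhere) and the attention stack.
#
# The pyramid: 1x1 laterals on C3-C5, top-down fusion by element addition
# with bilinear 2x up-sampling, a 3x3 refinement conv per fused level, and
# two stride-2 3x3 convs producing F6 and F7 (ReLU between the extra convs).
#
# The attention stack applies, n_blocks times, a cascade over the three
# non-spatial axes of the level x space x channel tensor:
#   level  (M_L): one scalar weight per pyramid level from pooled features,
#                 squashed by a hard sigmoid;
#   space  (M_S): cross-level aggregation at each spatial position through a
#                 modulated deformable 3x3 conv, offsets predicted from the
#                 un-resized target level, averaged over available neighbors;
#   channel(M_C): a dynamic piecewise-linear activation max(a1 x + b1,
#                 a2 x + b2) whose per-channel coefficients come from a
#                 two-layer bottleneck over globally pooled features,
#                 bounded to [-1, 1] and added to base values (1, 0, 0, 0).

define_fpn <- function(m) {
  cfg <- m$config
  fc <- cfg$fpn_channels
  ins <- cfg$stage_out_widths[2:4]
  for (i in 1:3) {
    def_conv(m, paste0("fpn.lat", i + 2), 1L, ins[i], fc)
    def_conv(m, paste0("fpn.out", i + 2), 3L, fc, fc)
  }
  def_conv(m, "fpn.p6", 3L, fc, fc, stride = 2L)
  def_conv(m, "fpn.p7", 3L, fc, fc, stride = 2L)
  invisible(NULL)
}

build_pyramid <- function(m, stages) {
  lat <- lapply(3:5, function(l)
    apply_conv(m, paste0("fpn.lat", l), stages[[paste0("C", l)]]))
  f5 <- lat[[3]]
  f4 <- apply_add(lat[[2]], apply_resize(f5, shape_of(lat[[2]])$h, shape_of(lat[[2]])$w))
  f3 <- apply_add(lat[[1]], apply_resize(f4, shape_of(lat[[1]])$h, shape_of(lat[[1]])$w))
  fused <- list(f3, f4, f5)
  outs <- lapply(1:3, function(i) apply_conv(m, paste0("fpn.out", i + 2), fused[[i]]))
  f6 <- apply_conv(m, "fpn.p6", outs[[3]])
  f7 <- apply_conv(m, "fpn.p7", apply_relu(f6))
  c(outs, list(f6, f7))
}

shape_of <- function(x) {
  if (is_shp(x)) x else { d <- dim(x$value); shp(d[1], d[2], d[3]) }
}

define_lsc <- function(m) {
  cfg <- m$config
  fc <- cfg$fpn_channels
  r <- cfg$lsc_reduction
  # near-identity start: the scale branch emits a constant 0.5, the spatial
  # aggregation passes the level through an identity kernel (neighbor
  # kernels zero), and the channel activation starts as plain ReLU - the
  # stack then learns its attentions instead of scrambling the pyramid
  # at initialization
  for (k in seq_len(cfg$lsc_blocks)) {
    nm <- sprintf("lsc.b%d", k)
    def_linear(m, paste0(nm, ".scale"), fc, 1L, init = "zero")
    def_conv(m, paste0(nm, ".off"), 3L, fc, 27L, init = "zero",
             bias_init = c(rep(0, 18), rep(cfg$mod_bias_init, 9)))
    if (cfg$lsc_share_neighbor_kernels) {
      def_conv(m, paste0(nm, ".sp_mid"), 3L, fc, fc, bias = FALSE,
               init = "identity")
    } else {
      def_conv(m, paste0(nm, ".sp_low"), 3L, fc, fc, bias = FALSE, init = "zero")
      def_conv(m, paste0(nm, ".sp_mid"), 3L, fc, fc, bias = FALSE,
               init = "identity")
      def_conv(m, paste0(nm, ".sp_high"), 3L, fc, fc, bias = FALSE, init = "zero")
    }
    def_linear(m, paste0(nm, ".ch_fc1"), fc, max(1L, fc %/% r))
    def_linear(m, paste0(nm, ".ch_fc2"), max(1L, fc %/% r), 4L * fc, init = "zero")
  }
  invisible(NULL)
}

# M_L: one hard-sigmoid scalar per level
scale_attention <- function(m, nm, pyr) {
  lapply(pyr, function(f) {
    v <- apply_gap(f)
    w <- apply_linear(m, paste0(nm, ".scale"), v)
    if (is_shp(f)) return(f)
    w <- ad_hard_sigmoid(ad_relu(w), m$config$hard_sigmoid["offset"],
                         m$config$hard_sigmoid["divisor"])
    ad_mul(f, w)
  })
}

# M_S: deformable cross-level aggregation at each level's own resolution
spatial_attention <- function(m, nm, pyr) {
  L <- length(pyr)
  share <- m$config$lsc_share_neighbor_kernels
  kname <- function(pos) paste0(nm, ".sp_", if (share) "mid" else pos)
  out <- vector("list", L)
  for (l in seq_len(L)) {
    f <- pyr[[l]]
    if (is_shp(f)) {
      # offset predictor is a standard conv: count it once per level
      invisible(apply_conv(m, paste0(nm, ".off"), f))
      out[[l]] <- f
      next
    }
    d <- dim(f$value)
    off_mod <- apply_conv(m, paste0(nm, ".off"), f)
    n_off <- 18L
    offs <- ad_reshape(ad_gather(off_mod, seq_len(d[1] * d[2] * n_off)),
                       c(d[1], d[2], n_off))
    mod <- ad_sigmoid(ad_reshape(
      ad_gather(off_mod, d[1] * d[2] * n_off + seq_len(d[1] * d[2] * 9L)),
      c(d[1], d[2], 9L)))
    members <- list()
    if (l > 1) {
      low <- apply_resize(pyr[[l - 1]], d[1], d[2])  # finer -> down to l
      members <- c(members, list(ad_deform_conv(low, p_(m, paste0(kname("low"), ".w")),
                                                NULL, offs, mod, 1L, 1L)))
    }
    members <- c(members, list(ad_deform_conv(f, p_(m, paste0(kname("mid"), ".w")),
                                              NULL, offs, mod, 1L, 1L)))
    if (l < L) {
      high <- apply_resize(pyr[[l + 1]], d[1], d[2])  # coarser -> up to l
      members <- c(members, list(ad_deform_conv(high, p_(m, paste0(kname("high"), ".w")),
                                                NULL, offs, mod, 1L, 1L)))
    }
    out[[l]] <- ad_list_mean(members)
  }
  out
}

# M_C: dynamic piecewise-linear activation from level+space pooled features
channel_attention <- function(m, nm, pyr) {
  if (is_shp(pyr[[1]])) {
    invisible(apply_linear(m, paste0(nm, ".ch_fc1"), shp(1, 1, pyr[[1]]$c)))
    invisible(apply_linear(m, paste0(nm, ".ch_fc2"),
                           shp(1, 1, max(1L, pyr[[1]]$c %/% m$config$lsc_reduction))))
    return(pyr)
  }
  pooled <- ad_list_mean(lapply(pyr, ad_gap))
  h <- ad_relu(apply_linear(m, paste0(nm, ".ch_fc1"), pooled))
  raw <- apply_linear(m, paste0(nm, ".ch_fc2"), h)
  norm <- ad_sub(ad_mul(ad_sigmoid(raw), 2), 1)      # [-1, 1]
  C <- length(pooled$value)
  gain <- 0.5
  take <- function(k) ad_gather(norm, (k - 1L) * C + seq_len(C))
  a1 <- ad_add(ad_mul(take(1L), gain), 1)
  a2 <- ad_mul(take(2L), gain)
  b1 <- ad_mul(take(3L), gain)
  b2 <- ad_mul(take(4L), gain)
  lapply(pyr, function(f) ad_dyn_relu(f, a1, b1, a2, b2))
}

lsc_stack <- function(m, pyr) {
  for (k in seq_len(m$config$lsc_blocks)) {
    nm <- sprintf("lsc.b%d", k)
    pyr <- scale_attention(m, nm, pyr)
    pyr <- spatial_attention(m, nm, pyr)
    pyr <- channel_attention(m, nm, pyr)
  }
  pyr
}
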