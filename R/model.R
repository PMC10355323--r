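# Detector configuration, parameter registry and layer wrappers.
#
# Every layer application goes through an apply_* wrapper that accepts either
# an autodiff node (real forward pass) or a lightweight shape descriptor
# (symbolic pass used by the complexity counter). The two passes therefore
# share a single topology definition and cannot drift apart.

#' Detector configuration
#'
#' Defaults reproduce the full model: ResNet50 backbone with modulated
#' deformable 3x3 convolutions in stages C3-C5, a 5-level 256-channel feature
#' pyramid, three stacked level/spatial/channel attention blocks, decoupled
#' shared heads, and dual-weighting label assignment. Switching `use_dcn`,
#' `use_lsc` off and `assigner = "fcos"` gives the plain-FCOS baseline
#' configuration.
#'
#' @param n_classes Number of object categories (1 for single-fruit data).
#' @param width_mult Width multiplier on every backbone channel count;
#'   fractions give the reduced desk-scale model.
#' @param fpn_channels Pyramid width (256 in the full model).
#' @param use_dcn Deformable 3x3 convolutions in backbone stages C3-C5.
#' @param use_lsc Attach the level/spatial/channel attention stack.
#' @param lsc_blocks Number of stacked attention blocks.
#' @param lsc_share_neighbor_kernels Share one deformable kernel across the
#'   lower/self/upper members of the spatial aggregation instead of three.
#' @param lsc_reduction Channel-attention bottleneck reduction factor.
#' @param head_convs Tower depth of the classification/regression heads.
#' @param prior_prob Classification bias prior preventing early focal-loss
#'   collapse.
#' @param assigner `"dual_weight"` or `"fcos"`.
#' @param assign_warmup_iters With the dual-weighting assigner, the number of
#'   initial training iterations supervised by the static center-sampling
#'   (focal + centerness) losses before switching to the dual weights. The
#'   weighting functions are proportional to the predicted score and to the
#'   IoU of the current decoded box, which carry no signal at random
#'   initialization; prediction-aware assigners in this detector family are
#'   conventionally warmed up with a static assigner for this reason. Set to
#'   0 to disable.
#' @param mu,beta,gamma Dual-weighting hyperparameters: positive-weight gap
#'   factor, IoU balancing exponent, negative modulation factor.
#' @param candidate_radius Center-sampling radius in units of level stride.
#' @param iou_lo,iou_hi Endpoints of the negative-probability interval; the
#'   linear segment is the unique line with `P_neg(iou_lo) = 1`,
#'   `P_neg(iou_hi) = 0`.
#' @param lambda Regression loss weight.
#' @param focal_alpha,focal_eta Focal loss balance and rate parameters.
#' @param score_mode `"fused"` uses the class probability times the predicted
#'   center-offset probability (the quantity ranked at test time) inside the
#'   weighting functions; `"cls"` uses the raw class probability.
#' @param strides Pyramid strides.
#' @param regress_ranges Level assignment bounds on the per-location maximum
#'   box-edge distance.
#' @param scale_init Initial value of the per-level learnable delta scale.
#' @return A `detector_config` list.
#' @export
detector_config <- function(n_classes = 1L,
                            width_mult = 1,
                            fpn_channels = 256L,
                            use_dcn = TRUE,
                            use_lsc = TRUE,
                            lsc_blocks = 3L,
                            lsc_share_neighbor_kernels = FALSE,
                            lsc_reduction = 4L,
                            head_convs = 4L,
                            prior_prob = 0.01,
                            assigner = c("dual_weight", "fcos"),
                            assign_warmup_iters = 500L,
                            mu = 5, beta = 2, gamma = 2,
                            candidate_radius = 1.5,
                            iou_lo = 0.5, iou_hi = 0.95,
                            lambda = 1,
                            focal_alpha = 0.25, focal_eta = 2,
                            score_mode = c("fused", "cls"),
                            strides = c(8L, 16L, 32L, 64L, 128L),
                            regress_ranges = c(0, 64, 128, 256, 512, Inf),
                            scale_init = 1) {
  assigner <- match.arg(assigner)
  score_mode <- match.arg(score_mode)
  widths <- as.integer(round(c(64, 128, 256, 512) * width_mult))
  structure(list(
    n_classes = as.integer(n_classes), width_mult = width_mult,
    stem_width = as.integer(round(64 * width_mult)),
    stage_mid_widths = widths, stage_out_widths = widths * 4L,
    stage_blocks = c(3L, 4L, 6L, 3L),
    fpn_channels = as.integer(fpn_channels),
    use_dcn = use_dcn, use_lsc = use_lsc,
    lsc_blocks = as.integer(lsc_blocks),
    lsc_share_neighbor_kernels = lsc_share_neighbor_kernels,
    lsc_reduction = as.integer(lsc_reduction),
    head_convs = as.integer(head_convs), prior_prob = prior_prob,
    assigner = assigner,
    assign_warmup_iters = as.integer(assign_warmup_iters),
    mu = mu, beta = beta, gamma = gamma,
    candidate_radius = candidate_radius, iou_lo = iou_lo, iou_hi = iou_hi,
    lambda = lambda, focal_alpha = focal_alpha, focal_eta = focal_eta,
    score_mode = score_mode,
    strides = strides, regress_ranges = regress_ranges,
    scale_init = scale_init,
    hard_sigmoid = c(offset = 3, divisor = 6),
    mod_bias_init = 12  # sigmoid(12) ~ 1: deformable convs start as plain convs
  ), class = "detector_config")
}

# ---- parameter registry -----------------------------------------------------

new_model <- function(config) {
  m <- new.env(parent = emptyenv())
  m$config <- config
  m$params <- new.env(parent = emptyenv())
  m$param_names <- character()
  m$meta <- new.env(parent = emptyenv())
  class(m) <- "fcos_lsc_model"
  m
}

#' @export
print.fcos_lsc_model <- function(x, ...) {
  n <- sum(vapply(x$param_names,
                  function(nm) length(x$params[[nm]]$value), numeric(1)))
  cat(sprintf("<fcos_lsc_model> %d parameter tensors, %.2fM scalars\n",
              length(x$param_names), n / 1e6))
  invisible(x)
}

reg_param <- function(m, name, value) {
  m$params[[name]] <- ad_param(value)
  m$param_names <- c(m$param_names, name)
  invisible(NULL)
}

p_ <- function(m, name) {
  v <- m$params[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  v
}

he_init <- function(k, cin, cout, gain = 2) {
  array(rnorm(k * k * cin * cout, sd = sqrt(gain / (k * k * cin))),
        c(k, k, cin, cout))
}

# conv layer: registers weights + optional bias and records metadata.
# In skeleton mode (complexity counting) only scalar counts are recorded,
# no arrays are allocated.
def_conv <- function(m, name, k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L,
                     bias = TRUE, init = c("he", "zero", "identity"),
                     bias_init = 0) {
  init <- match.arg(init)
  if (isTRUE(m$skeleton)) {
    m$n_scalars <- m$n_scalars + k * k * cin * cout + if (bias) cout else 0
  } else {
    w <- switch(init,
      he = he_init(k, cin, cout),
      zero = array(0, c(k, k, cin, cout)),
      identity = {
        stopifnot(cin == cout)
        a <- array(0, c(k, k, cin, cout))
        mid <- (k + 1L) %/% 2L
        for (c in seq_len(cin)) a[mid, mid, c, c] <- 1
        a
      })
    reg_param(m, paste0(name, ".w"), w)
    if (bias) reg_param(m, paste0(name, ".b"), rep(bias_init, length.out = cout))
  }
  m$meta[[name]] <- list(type = "conv", k = k, cin = cin, cout = cout,
                         stride = stride, pad = pad, bias = bias)
  invisible(NULL)
}

def_gn <- function(m, name, c) {
  if (isTRUE(m$skeleton)) {
    m$n_scalars <- m$n_scalars + 2 * c
  } else {
    reg_param(m, paste0(name, ".g"), rep(1, c))
    reg_param(m, paste0(name, ".be"), rep(0, c))
  }
  m$meta[[name]] <- list(type = "gn", c = c, groups = gn_groups(c))
  invisible(NULL)
}

def_linear <- function(m, name, cin, cout, bias = TRUE,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  if (isTRUE(m$skeleton)) {
    m$n_scalars <- m$n_scalars + cin * cout + if (bias) cout else 0
  } else {
    w <- if (init == "he") matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
         else matrix(0, cin, cout)
    reg_param(m, paste0(name, ".w"), w)
    if (bias) reg_param(m, paste0(name, ".b"), rep(0, cout))
  }
  m$meta[[name]] <- list(type = "linear", cin = cin, cout = cout, bias = bias)
  invisible(NULL)
}

def_scalar <- function(m, name, value) {
  if (isTRUE(m$skeleton)) {
    m$n_scalars <- m$n_scalars + length(value)
  } else {
    reg_param(m, name, value)
  }
  m$meta[[name]] <- list(type = "scalar")
  invisible(NULL)
}

build_skeleton <- function(config) {
  m <- new_model(config)
  m$skeleton <- TRUE
  m$n_scalars <- 0
  define_backbone(m)
  define_fpn(m)
  if (config$use_lsc) define_lsc(m)
  define_head(m)
  m
}

gn_groups <- function(c) {
  for (g in c(32L, 16L, 8L, 4L, 2L)) if (c %% g == 0 && g <= c) return(g)
  1L
}

# ---- shape-mode plumbing ----------------------------------------------------

shp <- function(h, w, c) structure(list(h = h, w = w, c = c), class = "shp")
is_shp <- function(x) inherits(x, "shp")
conv_out <- function(n, k, s, p) (n + 2 * p - k) %/% s + 1

flops_add <- function(m, macs) {
  if (!is.null(m$flops_acc)) m$flops_acc$macs <- m$flops_acc$macs + macs
  invisible(NULL)
}

apply_conv <- function(m, name, x) {
  mt <- m$meta[[name]]
  if (is_shp(x)) {
    ho <- conv_out(x$h, mt$k, mt$stride, mt$pad)
    wo <- conv_out(x$w, mt$k, mt$stride, mt$pad)
    flops_add(m, as.numeric(mt$k)^2 * mt$cin * mt$cout * ho * wo)
    return(shp(ho, wo, mt$cout))
  }
  b <- if (mt$bias) p_(m, paste0(name, ".b")) else NULL
  ad_conv2d(x, p_(m, paste0(name, ".w")), b, mt$stride, mt$pad)
}

# modulated deformable conv; offsets/modulation predicted by `offset_name`
# (a standard conv defined alongside). The sampling operation itself carries
# no entry in the FLOPs accumulator: the counter follows the common
# hook-based convention in which only standard conv/linear layers are
# instrumented, which is also the convention under which the reference
# complexity figures for this architecture family are mutually consistent.
apply_dconv <- function(m, name, offset_name, x) {
  mt <- m$meta[[name]]
  K2 <- mt$k^2
  off_mod <- apply_conv(m, offset_name, x)
  if (is_shp(x)) {
    ho <- conv_out(x$h, mt$k, mt$stride, mt$pad)
    wo <- conv_out(x$w, mt$k, mt$stride, mt$pad)
    return(shp(ho, wo, mt$cout))
  }
  d <- dim(off_mod$value)
  n_off <- 2L * K2
  offs <- ad_gather(off_mod, seq_len(d[1] * d[2] * n_off))
  offs <- ad_reshape(offs, c(d[1], d[2], n_off))
  mod_raw <- ad_gather(off_mod, d[1] * d[2] * n_off + seq_len(d[1] * d[2] * K2))
  mod <- ad_sigmoid(ad_reshape(mod_raw, c(d[1], d[2], K2)))
  b <- if (mt$bias) p_(m, paste0(name, ".b")) else NULL
  ad_deform_conv(x, p_(m, paste0(name, ".w")), b, offs, mod, mt$stride, mt$pad)
}

# fused conv + group norm (+ ReLU); one node on the tape
apply_conv_gn_relu <- function(m, conv_name, gn_name, x, relu = TRUE) {
  mt <- m$meta[[conv_name]]
  if (is_shp(x)) return(apply_conv(m, conv_name, x))
  gt <- m$meta[[gn_name]]
  ad_conv_gn_relu(x, p_(m, paste0(conv_name, ".w")),
                  p_(m, paste0(gn_name, ".g")), p_(m, paste0(gn_name, ".be")),
                  stride = mt$stride, pad = mt$pad, groups = gt$groups,
                  relu = relu)
}

apply_gn_relu <- function(m, name, x, relu = TRUE) {
  if (is_shp(x)) return(x)
  mt <- m$meta[[name]]
  ad_gn_relu(x, p_(m, paste0(name, ".g")), p_(m, paste0(name, ".be")),
             mt$groups, relu = relu)
}

apply_gn <- function(m, name, x) {
  if (is_shp(x)) return(x)
  mt <- m$meta[[name]]
  ad_group_norm(x, p_(m, paste0(name, ".g")), p_(m, paste0(name, ".be")),
                mt$groups)
}

apply_linear <- function(m, name, x) {
  mt <- m$meta[[name]]
  if (is_shp(x)) {
    flops_add(m, as.numeric(mt$cin) * mt$cout)
    return(shp(1, 1, mt$cout))
  }
  b <- if (mt$bias) p_(m, paste0(name, ".b")) else NULL
  ad_linear(x, p_(m, paste0(name, ".w")), b)
}

apply_relu <- function(x) if (is_shp(x)) x else ad_relu(x)

apply_add <- function(a, b) if (is_shp(a)) a else ad_add(a, b)

apply_maxpool <- function(x, k = 3L, stride = 2L, pad = 1L) {
  if (is_shp(x))
    return(shp(conv_out(x$h, k, stride, pad), conv_out(x$w, k, stride, pad), x$c))
  ad_maxpool(x, k, stride, pad)
}

apply_resize <- function(x, h, w) {
  if (is_shp(x)) return(shp(h, w, x$c))
  ad_resize(x, h, w)
}

apply_gap <- function(x) if (is_shp(x)) shp(1, 1, x$c) else ad_gap(x)

ad_reshape <- function(a, dims) {
  ad_op(array(a$value, dims), list(a), function(g) list(as.numeric(g)))
}

# ---- model assembly ---------------------------------------------------------

#' Build a detector with freshly initialized weights
#'
#' Convolutions use seeded He initialization; offset/modulation branches are
#' zero-initialized with a large modulation bias so every deformable
#' convolution starts out exactly equivalent to its plain counterpart; the
#' final classification bias encodes the `prior_prob` detection prior.
#'
#' @param config A [detector_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `fcos_lsc_model`.
#' @export
build_detector <- function(config = detector_config(), seed = 0L) {
  m <- new_model(config)
  with_local_seed(seed, {
    define_backbone(m)
    define_fpn(m)
    if (config$use_lsc) define_lsc(m)
    define_head(m)
  })
  m
}

#' Save / load model checkpoints
#'
#' Checkpoints carry a schema id, the builder configuration and every
#' parameter tensor including offset branches.
#'
#' @param model An `fcos_lsc_model`.
#' @param path File path.
#' @return `load_checkpoint()` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  values <- lapply(setNames(model$param_names, model$param_names),
                   function(nm) model$params[[nm]]$value)
  saveRDS(list(schema = "fcoslsc-checkpoint-1", config = model$config,
               values = values), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$schema, "fcoslsc-checkpoint-1"))
    stop("unrecognized checkpoint schema")
  m <- build_detector(ck$config, seed = 0L)
  for (nm in m$param_names) {
    if (is.null(ck$values[[nm]])) stop("checkpoint missing parameter ", nm)
    m$params[[nm]]$value <- ck$values[[nm]]
  }
  m
}

n_params <- function(model) {
  sum(vapply(model$param_names,
             function(nm) length(model$params[[nm]]$value), numeric(1)))
}
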