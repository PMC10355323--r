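# ResNet50 feature extractor. Stages C3-C5 replace the 3x3 conv of every
# bottleneck with a modulated deformable conv whose 27-channel offset branch
# (18 offsets + 9 modulation logits) is predicted by a zero-initialized
# standard conv over the same input. Normalization is group norm: the
# detector trains at batch size 2, where batch statistics are unusable.

define_backbone <- function(m) {
  cfg <- m$config
  sw <- cfg$stem_width
  def_conv(m, "bb.stem.conv", 7L, 3L, sw, stride = 2L, pad = 3L, bias = FALSE)
  def_gn(m, "bb.stem.gn", sw)
  cin <- sw
  for (s in 1:4) {
    mid <- cfg$stage_mid_widths[s]
    out <- cfg$stage_out_widths[s]
    stride <- if (s == 1) 1L else 2L
    dcn <- cfg$use_dcn && s >= 2  # stages C3, C4, C5
    for (b in seq_len(cfg$stage_blocks[s])) {
      nm <- sprintf("bb.s%d.b%d", s, b)
      bs <- if (b == 1) stride else 1L
      def_conv(m, paste0(nm, ".conv1"), 1L, cin, mid, bias = FALSE)
      def_gn(m, paste0(nm, ".gn1"), mid)
      def_conv(m, paste0(nm, ".conv2"), 3L, mid, mid, stride = bs, bias = FALSE)
      def_gn(m, paste0(nm, ".gn2"), mid)
      if (dcn)
        def_conv(m, paste0(nm, ".off2"), 3L, mid, 27L, stride = bs,
                 init = "zero", bias_init = c(rep(0, 18), rep(cfg$mod_bias_init, 9)))
      def_conv(m, paste0(nm, ".conv3"), 1L, mid, out, bias = FALSE)
      def_gn(m, paste0(nm, ".gn3"), out)
      if (b == 1) {
        def_conv(m, paste0(nm, ".down"), 1L, cin, out, stride = bs, bias = FALSE)
        def_gn(m, paste0(nm, ".down_gn"), out)
      }
      cin <- out
    }
  }
  invisible(NULL)
}

bottleneck_forward <- function(m, nm, x, dcn) {
  h <- apply_conv_gn_relu(m, paste0(nm, ".conv1"), paste0(nm, ".gn1"), x)
  h <- if (dcn) {
    apply_gn_relu(m, paste0(nm, ".gn2"),
                  apply_dconv(m, paste0(nm, ".conv2"), paste0(nm, ".off2"), h))
  } else {
    apply_conv_gn_relu(m, paste0(nm, ".conv2"), paste0(nm, ".gn2"), h)
  }
  h <- apply_conv_gn_relu(m, paste0(nm, ".conv3"), paste0(nm, ".gn3"), h,
                          relu = FALSE)
  idn <- if (!is.null(m$meta[[paste0(nm, ".down")]])) {
    apply_conv_gn_relu(m, paste0(nm, ".down"), paste0(nm, ".down_gn"), x,
                       relu = FALSE)
  } else x
  apply_relu(apply_add(h, idn))
}

# image (padded to /32) -> list(C2, C3, C4, C5) at strides 4/8/16/32
extract_stages <- function(m, x) {
  cfg <- m$config
  if (!is_shp(x) && dim(x$value)[3] != 3) stop("extract_stages: need 3-channel input")
  h <- apply_conv_gn_relu(m, "bb.stem.conv", "bb.stem.gn", x)
  h <- apply_maxpool(h)
  stages <- list()
  for (s in 1:4) {
    dcn <- cfg$use_dcn && s >= 2
    for (b in seq_len(cfg$stage_blocks[s]))
      h <- bottleneck_forward(m, sprintf("bb.s%d.b%d", s, b), h, dcn)
    stages[[paste0("C", s + 1)]] <- h
  }
  stages
}
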