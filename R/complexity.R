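# Symbolic parameter and FLOP counting. Parameters are counted from the
# layer registry without allocating weights; FLOPs come from a shape-only
# pass through the very same forward topology as the real model, so the
# counter cannot drift from the implementation.

#' Model complexity: parameter count and FLOPs
#'
#' Counts trainable scalars and the multiply-accumulate operations of all
#' standard convolution and fully connected layers at the stated input size
#' (one MAC counted as one FLOP; normalization, activations and pooling are
#' excluded). Feature sizes follow the exact convolution arithmetic of the
#' network with no padding of the input to a stride multiple. Deformable
#' sampling operations are not instrumented - the convention of the common
#' hook-based complexity counters for this architecture family - but the
#' standard convolutions predicting their offsets are counted.
#'
#' @param config A [detector_config()].
#' @param input_size `c(width, height)` pixels; default `c(600, 400)`.
#' @return One-row tibble: `params` (count), `params_m` (millions), `macs`,
#'   `gflops`, plus the input size.
#' @export
model_complexity <- function(config = detector_config(),
                             input_size = c(600, 400)) {
  m <- build_skeleton(config)
  m$flops_acc <- new.env(parent = emptyenv())
  m$flops_acc$macs <- 0
  invisible(detector_forward(m, shp(input_size[2], input_size[1], 3)))
  tibble::tibble(params = m$n_scalars, params_m = m$n_scalars / 1e6,
                 macs = m$flops_acc$macs, gflops = m$flops_acc$macs / 1e9,
                 input_width = input_size[1], input_height = input_size[2])
}
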