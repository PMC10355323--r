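# Training: SGD with momentum and weight decay, linear warmup and a stepped
# learning-rate schedule.

#' Training configuration
#'
#' Defaults are the full-scale recipe: base learning rate 0.00125 reached by
#' linear warmup from 0.001 over the first 1000 iterations, SGD momentum 0.9,
#' weight decay 0.0001, batch size 2, 12 epochs with tenfold learning-rate
#' drops at the start of the 8th and 11th epochs (1-based).
#'
#' @param base_lr,warmup_start_lr,warmup_iters Warmup schedule.
#' @param momentum,weight_decay SGD parameters.
#' @param epochs Total epochs.
#' @param step_epochs 1-based epochs at whose start the rate drops.
#' @param step_factor Multiplicative drop.
#' @param batch_size Images per iteration.
#' @param seed Seed covering data order, flips and any stochastic transform.
#' @param max_iterations Optional hard cap on the iteration count (the
#'   desk-scale benchmarks fix a budget rather than an epoch count).
#' @return A `train_config` list.
#' @export
train_config <- function(base_lr = 0.00125, warmup_start_lr = 0.001,
                         warmup_iters = 1000L, momentum = 0.9,
                         weight_decay = 1e-4, epochs = 12L,
                         step_epochs = c(8L, 11L), step_factor = 0.1,
                         batch_size = 2L, seed = 0L, max_iterations = NULL) {
  stopifnot(warmup_start_lr <= base_lr,
            all(diff(step_epochs) > 0), all(step_epochs <= epochs))
  structure(list(base_lr = base_lr, warmup_start_lr = warmup_start_lr,
                 warmup_iters = as.integer(warmup_iters), momentum = momentum,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 step_epochs = as.integer(step_epochs),
                 step_factor = step_factor,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 max_iterations = max_iterations),
            class = "train_config")
}

#' Learning rate at a given iteration
#'
#' Linear interpolation from `warmup_start_lr` to `base_lr` over
#' `[0, warmup_iters)`, then the base rate multiplied by
#' `step_factor^(number of step epochs already started)`. Epochs are 1-based;
#' the k-th epoch starts at iteration `(k-1) * epoch_length`.
#'
#' @param iteration 0-based iteration counter.
#' @param epoch_length Iterations per epoch.
#' @param cfg A [train_config()].
#' @return The scalar learning rate.
#' @export
lr_at <- function(iteration, epoch_length, cfg = train_config()) {
  stopifnot(iteration >= 0)
  lr <- if (iteration < cfg$warmup_iters) {
    cfg$warmup_start_lr +
      (cfg$base_lr - cfg$warmup_start_lr) * iteration / cfg$warmup_iters
  } else cfg$base_lr
  n_drops <- sum(iteration >= (cfg$step_epochs - 1L) * epoch_length)
  lr * cfg$step_factor^n_drops
}

# fetch one sample (image array + boxes) from a coco_dataset
load_sample <- function(data, image_id) {
  row <- which(data$images$image_id == image_id)
  arrays <- attr(data, "images_data")
  img <- if (!is.null(arrays) && length(arrays) >= row && !is.null(arrays[[row]])) {
    arrays[[row]]
  } else {
    read_image(file.path(data$dir, data$images$file_name[row]))
  }
  boxes <- data$annotations[data$annotations$image_id == image_id, ]
  list(image = img, boxes = boxes,
       width = data$images$width[row], height = data$images$height[row])
}

#' Train a detector
#'
#' Mini-batch SGD over a COCO dataset with the schedule of
#' [train_config()]. Fully seeded: data order, flips, and initialization
#' (via [build_detector()]) are reproducible. Aborts on a non-finite loss,
#' naming the iteration and component.
#'
#' @param model An `fcos_lsc_model` (modified in place and returned).
#' @param data A `coco_dataset`; images are taken from the in-memory
#'   attribute if present, else read from `data$dir`.
#' @param cfg A [train_config()].
#' @param target_size `c(width, height)` for preprocessing, or `NULL` to
#'   keep native sizes.
#' @param verbose Print a line every `verbose` iterations (0 = quiet).
#' @return An object of class `fcos_lsc_fit`: list with the trained `model`
#'   and the per-iteration `log` tibble (`iteration, lr, loss_total,
#'   loss_pos, loss_neg, loss_reg, n_pos`).
#' @export
train_detector <- function(model, data, cfg = train_config(),
                           target_size = NULL, verbose = 0L) {
  ids <- data$images$image_id
  stopifnot(length(ids) >= 1)
  epoch_length <- ceiling(length(ids) / cfg$batch_size)
  velocity <- new.env(parent = emptyenv())
  loc_cache <- new.env(parent = emptyenv())  # locations keyed by level shapes
  logs <- vector("list", epoch_length * cfg$epochs)
  iteration <- 0L
  max_it <- cfg$max_iterations %||% Inf
  for (epoch in seq_len(cfg$epochs)) {
    if (iteration >= max_it) break
    order <- with_local_seed(cfg$seed + epoch * 1009L, sample(ids))
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    for (batch in batches) {
      if (iteration >= max_it) break
      lr <- lr_at(iteration, epoch_length, cfg)
      batch_nodes <- list(); batch_logs <- list()
      for (bi in seq_along(batch)) {
        sm <- load_sample(data, batch[bi])
        ts <- target_size %||% c(sm$width, sm$height)
        pp <- preprocess_sample(sm, train_mode = TRUE, target_size = ts,
                                seed = cfg$seed + iteration * 131L + bi)
        x <- ad_const(pp$image)
        outs <- detector_forward(model, x)
        shp_key <- paste(vapply(attr(outs, "level_shapes"),
                                function(s) paste0(s$h, "x", s$w),
                                character(1)), collapse = ";")
        locs <- loc_cache[[shp_key]]
        if (is.null(locs)) {
          locs <- pyramid_locations(attr(outs, "level_shapes"),
                                    model$config$strides)
          loc_cache[[shp_key]] <- locs
        }
        dl <- detection_loss(model, outs, locs, pp$boxes,
                             pp$size["width"], pp$size["height"],
                             iteration = iteration)
        batch_nodes[[bi]] <- dl$node
        batch_logs[[bi]] <- dl$log
      }
      total <- ad_mul(Reduce(ad_add, batch_nodes), 1 / length(batch_nodes))
      lgm <- do.call(rbind, lapply(batch_logs, as.matrix))
      lg <- tibble::as_tibble(t(colMeans(lgm, na.rm = TRUE)))
      if (!is.finite(total$value)) {
        bad <- names(lg)[!is.finite(unlist(lg))]
        stop(sprintf("non-finite loss at iteration %d (%s)", iteration,
                     paste(bad, collapse = ", ")))
      }
      ad_backward(total)
      sgd_step(model, velocity, lr, cfg)
      logs[[iteration + 1L]] <- dplyr::bind_cols(
        tibble::tibble(iteration = iteration, epoch = epoch, lr = lr), lg)
      if (verbose > 0 && iteration %% verbose == 0)
        message(sprintf("iter %5d lr %.5f loss %.4f (pos %.3f neg %.3f reg %.3f)",
                        iteration, lr, lg$loss_total, lg$loss_pos,
                        lg$loss_neg, lg$loss_reg))
      iteration <- iteration + 1L
    }
  }
  structure(list(model = model,
                 log = dplyr::bind_rows(logs[!vapply(logs, is.null, logical(1))]),
                 config = cfg),
            class = "fcos_lsc_fit")
}

sgd_step <- function(model, velocity, lr, cfg) {
  for (nm in model$param_names) {
    par <- model$params[[nm]]
    g <- par$grad
    if (is.null(g)) next
    v <- velocity[[nm]]
    if (is.null(v)) v <- par$value * 0
    # value must be un-shared before the in-place update: copy once on the
    # first step after any external reference could have been taken
    if (!isTRUE(model$owned)) par$value <- par$value + 0
    cpp_sgd_update(par$value, g, v, lr, cfg$momentum, cfg$weight_decay)
    # store after the in-place write: assigning beforehand can leave a
    # duplicated (stale) array in the environment
    velocity[[nm]] <- v
    par$grad <- NULL
  }
  model$owned <- TRUE
  invisible(NULL)
}

#' @export
print.fcos_lsc_fit <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("<fcos_lsc_fit> %d iterations; final loss %.4f\n",
              n, x$log$loss_total[n]))
  invisible(x)
}

#' @rdname train_detector
#' @param x An `fcos_lsc_fit`.
#' @param ... Unused.
#' @export
tidy.fcos_lsc_fit <- function(x, ...) x$log

#' @rdname train_detector
#' @export
glance.fcos_lsc_fit <- function(x, ...) {
  lg <- x$log
  tibble::tibble(iterations = nrow(lg),
                 final_loss = lg$loss_total[nrow(lg)],
                 min_loss = min(lg$loss_total),
                 final_lr = lg$lr[nrow(lg)])
}

#' @rdname train_detector
#' @param object An `fcos_lsc_fit`.
#' @export
autoplot.fcos_lsc_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$log,
                              c("loss_total", "loss_pos", "loss_neg", "loss_reg"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "loss",
                  title = "Training loss components") +
    ggplot2::theme_minimal()
}
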