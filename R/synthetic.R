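# Seeded synthetic green-on-green orchard scenes with COCO ground truth.
# Scenes emulate the conditions green-fruit detectors face in the field:
# fruit hue barely separated from the canopy hue, fruit-fruit overlap,
# branch-like occluding strokes, global lighting regimes and distance blur.
# Boxes annotate the *visible* extent of each fruit; fruits with visible
# fraction below `min_visible_fraction` are not annotated.

#' Configuration for the synthetic orchard scene generator
#'
#' All sizes are pixels. `fruit_hue_offset` (degrees) is the hue gap between
#' fruit and canopy: small values give the hard green-on-green regime, large
#' values an easy benchmark. Rendering happens in HSV so this is a single
#' hardness knob. The same config and seed always render byte-identical
#' scenes; image `index` only shifts the seed, so datasets are extendable.
#'
#' @param image_size `c(width, height)`; default 600 x 400, the working
#'   resolution of the detector.
#' @param fruit_count_range Integer range of fruits per scene.
#' @param fruit_radius_range Range of fruit semi-major axes.
#' @param fruit_hue_offset Degrees of hue separating fruit from background.
#' @param occluder_count_range Integer range of branch/leaf strokes drawn
#'   above the fruit.
#' @param overlap_probability Probability that a fruit is deliberately placed
#'   intersecting a previously placed fruit.
#' @param lighting_mode One of `"soft"`, `"strong"`, `"backlight"`,
#'   `"low_light"`.
#' @param blur_sigma_range Range of the Gaussian blur sigma emulating
#'   capture distance.
#' @param min_visible_fraction Fruits whose visible fraction falls below this
#'   are left unannotated; default 0.25.
#' @param seed Integer; per-image seed is `seed + index`.
#' @return A `scene_config` list.
#' @export
scene_config <- function(image_size = c(600, 400),
                         fruit_count_range = c(2, 8),
                         fruit_radius_range = c(18, 50),
                         fruit_hue_offset = 15,
                         occluder_count_range = c(1, 4),
                         overlap_probability = 0.3,
                         lighting_mode = c("soft", "strong", "backlight", "low_light"),
                         blur_sigma_range = c(0, 1.5),
                         min_visible_fraction = 0.25,
                         seed = 0L) {
  lighting_mode <- match.arg(lighting_mode)
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            fruit_count_range[1] <= fruit_count_range[2],
            fruit_radius_range[1] <= fruit_radius_range[2],
            occluder_count_range[1] <= occluder_count_range[2],
            overlap_probability >= 0, overlap_probability <= 1,
            blur_sigma_range[1] <= blur_sigma_range[2],
            min_visible_fraction > 0, min_visible_fraction <= 1)
  if (fruit_radius_range[2] > min(image_size) / 2)
    stop("scene_config: fruit radius exceeds half the image")
  structure(list(image_size = as.integer(image_size),
                 fruit_count_range = as.integer(fruit_count_range),
                 fruit_radius_range = fruit_radius_range,
                 fruit_hue_offset = fruit_hue_offset,
                 occluder_count_range = as.integer(occluder_count_range),
                 overlap_probability = overlap_probability,
                 lighting_mode = lighting_mode,
                 blur_sigma_range = blur_sigma_range,
                 min_visible_fraction = min_visible_fraction,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# vectorized HSV (h in degrees, s/v in [0,1]) to an RGB array
hsv_to_rgb_array <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- v
  idx <- i == 0; r[idx] <- v[idx]; g[idx] <- t[idx]; b[idx] <- p[idx]
  idx <- i == 1; r[idx] <- q[idx]; g[idx] <- v[idx]; b[idx] <- p[idx]
  idx <- i == 2; r[idx] <- p[idx]; g[idx] <- v[idx]; b[idx] <- t[idx]
  idx <- i == 3; r[idx] <- p[idx]; g[idx] <- q[idx]; b[idx] <- v[idx]
  idx <- i == 4; r[idx] <- t[idx]; g[idx] <- p[idx]; b[idx] <- v[idx]
  idx <- i >= 5; r[idx] <- v[idx]; g[idx] <- p[idx]; b[idx] <- q[idx]
  d <- dim(h)
  array(c(r, g, b), c(d[1], d[2], 3))
}

# smooth random field in [-1, 1] from a coarse seeded grid
smooth_noise <- function(h, w, cells = 8) {
  coarse <- array(runif(cells * cells, -1, 1), c(cells, cells, 1))
  drop(cpp_resize_bilinear(coarse, as.integer(h), as.integer(w)))
}

gaussian_blur <- function(img, sigma) {
  if (sigma < 0.05) return(img)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  h <- dim(img)[1]; w <- dim(img)[2]
  # separable pass; zero padding renormalized near borders by blurring a
  # constant plane with the same kernel
  ones <- array(1, c(h, w, 1))
  kern2d <- array(outer(k, k), c(2 * r + 1, 2 * r + 1, 1, 1))
  norm <- cpp_conv2d(ones, kern2d, numeric(0), 1L, as.integer(r))
  out <- img
  for (c in seq_len(dim(img)[3])) {
    ch <- array(img[, , c], c(h, w, 1))
    sm <- cpp_conv2d(ch, kern2d, numeric(0), 1L, as.integer(r))
    out[, , c] <- sm[, , 1] / norm[, , 1]
  }
  out
}

#' Render one synthetic orchard scene
#'
#' @param config A [scene_config()].
#' @param index Image index; the per-image seed is `config$seed + index`.
#' @return List with `image` (H x W x 3 RGB array in `[0,1]`), `boxes`
#'   (tibble of visible-extent corner boxes with `category_id = 1` and the
#'   per-fruit `visible_fraction`), `all_fruits` (every rendered fruit,
#'   annotated or not), and `masks` (logical visibility masks).
#' @export
render_scene <- function(config, index = 1L) {
  stopifnot(inherits(config, "scene_config"))
  with_local_seed(config$seed + as.integer(index), render_scene_impl(config))
}

render_scene_impl <- function(cfg) {
  w <- cfg$image_size[1]; h <- cfg$image_size[2]
  bg_hue <- 110 + runif(1, -8, 8)        # canopy green
  # background HSV
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  H <- bg_hue + 6 * smooth_noise(h, w, 8)
  S <- 0.45 + 0.12 * smooth_noise(h, w, 6)
  V <- 0.38 + 0.14 * smooth_noise(h, w, 5) + 0.08 * (ys / h - 0.5)
  # fruits
  n_fruit <- sample(cfg$fruit_count_range[1]:cfg$fruit_count_range[2], 1)
  fruits <- list()
  for (i in seq_len(n_fruit)) {
    r <- runif(1, cfg$fruit_radius_range[1], cfg$fruit_radius_range[2])
    aspect <- runif(1, 0.85, 1.18)
    rx <- r; ry <- r * aspect
    if (i > 1 && runif(1) < cfg$overlap_probability) {
      prev <- fruits[[sample(i - 1, 1)]]
      ang <- runif(1, 0, 2 * pi)
      d <- runif(1, 0.4, 0.9) * (prev$rx + rx)
      cx <- min(max(prev$cx + d * cos(ang), rx), w - rx)
      cy <- min(max(prev$cy + d * sin(ang), ry), h - ry)
    } else {
      cx <- runif(1, rx, w - rx)
      cy <- runif(1, ry, h - ry)
    }
    fruits[[i]] <- list(cx = cx, cy = cy, rx = rx, ry = ry,
                        hl = runif(2, -0.4, 0.4))  # highlight offset
  }
  fruit_masks <- lapply(fruits, function(f)
    ((xs - f$cx) / f$rx)^2 + ((ys - f$cy) / f$ry)^2 <= 1)
  # paint fruits in order; later fruits overwrite (sit in front)
  for (i in seq_along(fruits)) {
    f <- fruits[[i]]; m <- fruit_masks[[i]]
    if (!any(m)) next
    dist <- sqrt(((xs - f$cx) / f$rx - f$hl[1])^2 +
                 ((ys - f$cy) / f$ry - f$hl[2])^2)
    shade <- pmax(0, 1 - 0.45 * dist)
    H[m] <- bg_hue + cfg$fruit_hue_offset + runif(1, -2, 2)
    S[m] <- 0.55 + 0.1 * runif(1)
    V[m] <- (0.45 + 0.35 * shade[m]) * runif(1, 0.9, 1.1)
  }
  # occluders: elongated darker-green strokes above the fruit
  occ_mask <- matrix(FALSE, h, w)
  n_occ <- sample(cfg$occluder_count_range[1]:cfg$occluder_count_range[2], 1)
  for (k in seq_len(n_occ)) {
    x0 <- runif(1, 0, w); y0 <- runif(1, 0, h)
    ang <- runif(1, 0, pi)
    len <- runif(1, 0.25, 0.8) * min(w, h)
    x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
    hw <- runif(1, 2, max(3, min(w, h) / 40))  # half-width
    # distance from each pixel to the segment
    vx <- x1 - x0; vy <- y1 - y0
    tt <- pmin(pmax(((xs - x0) * vx + (ys - y0) * vy) / (vx^2 + vy^2), 0), 1)
    d2 <- (xs - (x0 + tt * vx))^2 + (ys - (y0 + tt * vy))^2
    m <- d2 <= hw^2
    occ_mask <- occ_mask | m
    H[m] <- bg_hue - 12 + runif(1, -4, 4)
    S[m] <- 0.5
    V[m] <- V[m] * 0.45
  }
  # lighting
  V <- switch(cfg$lighting_mode,
    soft = V,
    strong = pmin(V * 1.3 + 0.08, 1),
    backlight = V * matrix(rep(seq(1.25, 0.5, length.out = w), each = h), h, w),
    low_light = V * 0.45)
  V <- pmin(pmax(V, 0), 1); S <- pmin(pmax(S, 0), 1)
  img <- hsv_to_rgb_array(H, S, V)
  sigma <- runif(1, cfg$blur_sigma_range[1], cfg$blur_sigma_range[2])
  img <- gaussian_blur(img, sigma)
  img <- pmin(pmax(img, 0), 1)
  # visibility: fruit i is hidden by fruits painted after it and by occluders
  vis_masks <- fruit_masks
  for (i in seq_along(fruits)) {
    m <- fruit_masks[[i]]
    if (i < length(fruits))
      for (j in (i + 1):length(fruits)) m <- m & !fruit_masks[[j]]
    vis_masks[[i]] <- m & !occ_mask
  }
  rows <- lapply(seq_along(fruits), function(i) {
    tot <- sum(fruit_masks[[i]])
    vis <- sum(vis_masks[[i]])
    frac <- if (tot > 0) vis / tot else 0
    if (vis == 0) return(NULL)
    px <- which(vis_masks[[i]], arr.ind = TRUE)
    tibble::tibble(fruit = i,
                   x_min = min(px[, 2]) - 1, y_min = min(px[, 1]) - 1,
                   x_max = max(px[, 2]), y_max = max(px[, 1]),
                   category_id = 1L, visible_fraction = frac)
  })
  all_fruits <- dplyr::bind_rows(rows)
  boxes <- if (nrow(all_fruits))
    all_fruits[all_fruits$visible_fraction >= cfg$min_visible_fraction, ]
  else all_fruits
  list(image = img, boxes = boxes, all_fruits = all_fruits, masks = vis_masks)
}

#' Generate a synthetic orchard dataset on disk
#'
#' Renders `n_images` seeded scenes, writes them as PNG plus one COCO
#' `annotations.json`, and returns the dataset. Per-image seeds are
#' `config$seed + index`, so two calls with the same config are identical and
#' a dataset can be extended without reshuffling existing images.
#'
#' @param config A [scene_config()].
#' @param n_images Number of images (>= 1).
#' @param out_dir Output directory (created if missing). `NULL` keeps the
#'   dataset in memory only.
#' @return A `coco_dataset`; rendered images are attached as attribute
#'   `images_data` (a list of arrays) for in-memory training.
#' @export
generate_dataset <- function(config, n_images, out_dir = NULL) {
  stopifnot(n_images >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  imgs <- list(); anns <- list(); arrays <- list()
  ann_id <- 0L
  for (i in seq_len(n_images)) {
    sc <- render_scene(config, i)
    fn <- sprintf("img_%06d.png", i)
    if (!is.null(out_dir)) png::writePNG(sc$image, file.path(out_dir, fn))
    arrays[[i]] <- sc$image
    imgs[[i]] <- tibble::tibble(image_id = i, file_name = fn,
                                width = config$image_size[1],
                                height = config$image_size[2])
    if (nrow(sc$boxes)) {
      b <- sc$boxes
      b$ann_id <- ann_id + seq_len(nrow(b))
      ann_id <- ann_id + nrow(b)
      b$image_id <- i
      anns[[length(anns) + 1L]] <-
        b[, c("ann_id", "image_id", "category_id",
              "x_min", "y_min", "x_max", "y_max")]
    }
  }
  annotations <- if (length(anns)) dplyr::bind_rows(anns) else empty_annotations()
  data <- new_coco_dataset(dplyr::bind_rows(imgs), annotations,
                           tibble::tibble(category_id = 1L, name = "fruit"),
                           dir = out_dir)
  if (!is.null(out_dir)) write_coco(data, file.path(out_dir, "annotations.json"))
  attr(data, "images_data") <- arrays
  data
}
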