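# COCO-format detection datasets as a list of three tibbles
# (images, annotations, categories), plus LabelMe conversion, seeded
# splitting and the training-time preprocessing pipeline.

new_coco_dataset <- function(images, annotations, categories, dir = NULL) {
  structure(list(images = images, annotations = annotations,
                 categories = categories, dir = dir),
            class = "coco_dataset")
}

#' @export
print.coco_dataset <- function(x, ...) {
  cat(sprintf("<coco_dataset> %d images, %d annotations, %d categories\n",
              nrow(x$images), nrow(x$annotations), nrow(x$categories)))
  invisible(x)
}

#' Read a COCO detection JSON file
#'
#' Parses the standard `images` / `annotations` / `categories` arrays into
#' tibbles. COCO `[x, y, width, height]` boxes are converted to continuous
#' corner coordinates (`x_min, y_min, x_max, y_max`).
#'
#' @param path Path to a COCO JSON file.
#' @return A `coco_dataset`: list of tibbles `images` (`image_id, file_name,
#'   width, height`), `annotations` (`ann_id, image_id, category_id`, corner
#'   coordinates), and `categories` (`category_id, name`).
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop("read_coco: no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (k in c("images", "annotations", "categories"))
    if (is.null(doc[[k]])) stop("read_coco: missing '", k, "' array")
  images <- tibble::tibble(
    image_id = as.integer(doc$images$id),
    file_name = as.character(doc$images$file_name),
    width = as.integer(doc$images$width),
    height = as.integer(doc$images$height)
  )
  ann <- doc$annotations
  if (length(ann) && NROW(ann) > 0) {
    bbox <- if (is.matrix(ann$bbox)) ann$bbox else do.call(rbind, ann$bbox)
    bad <- setdiff(unique(as.integer(ann$image_id)), images$image_id)
    if (length(bad))
      stop("read_coco: annotation references unknown image_id: ",
           paste(bad, collapse = ", "))
    annotations <- tibble::tibble(
      ann_id = as.integer(ann$id),
      image_id = as.integer(ann$image_id),
      category_id = as.integer(ann$category_id),
      x_min = bbox[, 1], y_min = bbox[, 2],
      x_max = bbox[, 1] + bbox[, 3], y_max = bbox[, 2] + bbox[, 4]
    )
  } else {
    annotations <- empty_annotations()
  }
  categories <- tibble::tibble(
    category_id = as.integer(doc$categories$id),
    name = as.character(doc$categories$name)
  )
  new_coco_dataset(images, annotations, categories, dir = dirname(path))
}

empty_annotations <- function() {
  tibble::tibble(ann_id = integer(), image_id = integer(),
                 category_id = integer(), x_min = double(), y_min = double(),
                 x_max = double(), y_max = double())
}

#' Write a dataset back to COCO JSON
#'
#' Inverse of [read_coco()]: corner boxes are serialized as COCO
#' `[x, y, width, height]`.
#'
#' @param data A `coco_dataset`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(data, path) {
  ann <- data$annotations
  doc <- list(
    images = lapply(seq_len(nrow(data$images)), function(i) {
      r <- data$images[i, ]
      list(id = r$image_id, file_name = r$file_name,
           width = r$width, height = r$height)
    }),
    annotations = lapply(seq_len(nrow(ann)), function(i) {
      r <- ann[i, ]
      w <- r$x_max - r$x_min; h <- r$y_max - r$y_min
      list(id = r$ann_id, image_id = r$image_id, category_id = r$category_id,
           bbox = c(r$x_min, r$y_min, w, h), area = w * h, iscrowd = 0L)
    }),
    categories = lapply(seq_len(nrow(data$categories)), function(i) {
      r <- data$categories[i, ]
      list(id = r$category_id, name = r$name)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert a directory of LabelMe JSON files to a COCO dataset
#'
#' Each LabelMe shape (polygon or rectangle) becomes one annotation whose box
#' is the tight axis-aligned bound of its points. Image and annotation ids are
#' assigned deterministically: files sorted by name, shapes in file order.
#'
#' @param dir Directory containing `*.json` LabelMe files.
#' @param category_map Named integer vector mapping LabelMe labels to COCO
#'   category ids; unlisted labels get fresh ids in label sort order.
#' @return A `coco_dataset`; the number of skipped degenerate shapes (fewer
#'   than 2 points) is attached as attribute `skipped`.
#' @export
convert_labelme <- function(dir, category_map = NULL) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("convert_labelme: no JSON files in ", dir)
  images <- list(); anns <- list(); skipped <- 0L
  labels <- character()
  ann_id <- 0L
  for (i in seq_along(files)) {
    doc <- jsonlite::fromJSON(files[[i]], simplifyVector = FALSE)
    images[[i]] <- tibble::tibble(
      image_id = i,
      file_name = doc$imagePath %||% sub("\\.json$", ".png", basename(files[[i]])),
      width = as.integer(doc$imageWidth), height = as.integer(doc$imageHeight))
    for (sh in doc$shapes) {
      pts <- do.call(rbind, lapply(sh$points, unlist))
      if (is.null(pts) || nrow(pts) < 2) {
        warning("convert_labelme: shape with <2 points skipped in ",
                basename(files[[i]]))
        skipped <- skipped + 1L
        next
      }
      labels <- union(labels, sh$label)
      ann_id <- ann_id + 1L
      anns[[length(anns) + 1L]] <- tibble::tibble(
        ann_id = ann_id, image_id = i, label = sh$label,
        x_min = min(pts[, 1]), y_min = min(pts[, 2]),
        x_max = max(pts[, 1]), y_max = max(pts[, 2]))
    }
  }
  if (is.null(category_map)) {
    category_map <- setNames(seq_along(sort(labels)), sort(labels))
  }
  annotations <- dplyr::bind_rows(anns)
  if (nrow(annotations)) {
    annotations$category_id <- as.integer(category_map[annotations$label])
    annotations$label <- NULL
    annotations <- annotations[, c("ann_id", "image_id", "category_id",
                                   "x_min", "y_min", "x_max", "y_max")]
  } else {
    annotations <- empty_annotations()
  }
  categories <- tibble::tibble(category_id = as.integer(category_map),
                               name = names(category_map))
  out <- new_coco_dataset(dplyr::bind_rows(images), annotations, categories,
                          dir = dir)
  attr(out, "skipped") <- skipped
  out
}

round_half_up <- function(x) floor(x + 0.5)

#' Split a dataset into train and validation subsets
#'
#' Membership is a seeded random shuffle; the training size is the
#' round-half-up of `ratio * N` (so 1361 images at ratio 0.7 give 953/408).
#'
#' @param data A `coco_dataset`.
#' @param ratio Training proportion in (0, 1); default 0.7 (a 7:3 split).
#' @param seed Integer seed making membership reproducible.
#' @return List with `coco_dataset`s `train` and `val` plus the `ratio` pair.
#' @export
split_dataset <- function(data, ratio = 0.7, seed = 0L) {
  stopifnot(ratio > 0, ratio < 1)
  ids <- data$images$image_id
  n <- length(ids)
  if (n < 2) stop("split_dataset: need at least 2 images")
  n_train <- round_half_up(ratio * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  perm <- with_local_seed(seed, sample.int(n))
  train_ids <- sort(ids[perm[seq_len(n_train)]])
  val_ids <- sort(ids[perm[(n_train + 1L):n]])
  list(train = subset_coco(data, train_ids),
       val = subset_coco(data, val_ids),
       ratio = c(train = ratio, val = 1 - ratio))
}

subset_coco <- function(data, image_ids) {
  new_coco_dataset(
    images = data$images[data$images$image_id %in% image_ids, ],
    annotations = data$annotations[data$annotations$image_id %in% image_ids, ],
    categories = data$categories, dir = data$dir)
}

# run expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read a PNG or JPEG image as an H x W x 3 array in [0, 1]
#' @param path Image file path.
#' @return Numeric array `height x width x 3`.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}

# ImageNet-style per-channel normalization constants (RGB)
default_norm <- function() {
  list(mean = c(0.485, 0.456, 0.406), std = c(0.229, 0.224, 0.225))
}

#' Preprocess one image sample for training or inference
#'
#' Resizes to `target_size` (scaling boxes by the same factors), optionally
#' applies a seeded horizontal flip with probability 0.5 (training only),
#' normalizes each channel, and zero-pads right/bottom so both dimensions are
#' divisible by 32. Padding leaves box coordinates untouched. The returned
#' `ops` record makes every step invertible for visualization.
#'
#' @param sample List with `image` (H x W x 3 array in `[0,1]`) and `boxes`
#'   (tibble with corner coordinates and `category_id`).
#' @param train_mode Logical; enables the random flip.
#' @param target_size `c(width, height)` in pixels, default `c(600, 400)`.
#' @param seed Integer seed for the flip draw.
#' @param norm List with `mean` and `std` length-3 vectors.
#' @return List with transformed `image`, `boxes`, the padded size, and `ops`.
#' @export
preprocess_sample <- function(sample, train_mode = FALSE,
                              target_size = c(600, 400), seed = 0L,
                              norm = default_norm()) {
  stopifnot(all(target_size > 0))
  img <- sample$image
  h0 <- dim(img)[1]; w0 <- dim(img)[2]
  tw <- target_size[1]; th <- target_size[2]
  sx <- tw / w0; sy <- th / h0
  if (h0 != th || w0 != tw) img <- cpp_resize_bilinear(img, as.integer(th), as.integer(tw))
  boxes <- sample$boxes
  ops <- list(resize = c(sx = sx, sy = sy))
  if (!is.null(boxes) && nrow(boxes)) {
    boxes$x_min <- boxes$x_min * sx; boxes$x_max <- boxes$x_max * sx
    boxes$y_min <- boxes$y_min * sy; boxes$y_max <- boxes$y_max * sy
    keep <- (boxes$x_max - boxes$x_min) > 0 & (boxes$y_max - boxes$y_min) > 0
    if (any(!keep)) {
      warning("preprocess_sample: dropped ", sum(!keep), " zero-area box(es)")
      boxes <- boxes[keep, ]
    }
  }
  flipped <- FALSE
  if (train_mode) {
    flipped <- with_local_seed(seed, runif(1)) < 0.5
    if (flipped) {
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      if (!is.null(boxes) && nrow(boxes)) boxes <- flip_boxes(boxes, tw)
    }
  }
  ops$flip <- flipped
  for (c in 1:3) img[, , c] <- (img[, , c] - norm$mean[c]) / norm$std[c]
  ops$normalize <- norm
  ph <- ceiling(th / 32) * 32; pw <- ceiling(tw / 32) * 32
  if (ph != th || pw != tw) {
    padded <- array(0, c(ph, pw, 3))
    padded[seq_len(th), seq_len(tw), ] <- img
    img <- padded
  }
  ops$pad <- c(right = pw - tw, bottom = ph - th)
  list(image = img, boxes = boxes, size = c(width = tw, height = th),
       padded_size = c(width = pw, height = ph), ops = ops)
}
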