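test_that("read_coco converts xywh to corners and validates references", {
  path <- write_tiny_coco(tempfile(fileext = ".json"))
  ds <- read_coco(path)
  expect_equal(nrow(ds$images), 3)
  expect_equal(nrow(ds$annotations), 5)
  # bbox [10, 20, 30, 40] -> corners (10, 20, 40, 60)
  a1 <- ds$annotations[ds$annotations$ann_id == 1, ]
  expect_equal(c(a1$x_min, a1$y_min, a1$x_max, a1$y_max), c(10, 20, 40, 60))
  # cross-check totals against an independent JSON parse
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(nrow(ds$images), length(raw$images))
  expect_equal(nrow(ds$annotations), length(raw$annotations))
  per_image <- table(ds$annotations$image_id)
  raw_per <- table(vapply(raw$annotations, function(a) a$image_id, numeric(1)))
  expect_equal(as.integer(per_image), as.integer(raw_per))
  expect_error(read_coco(tempfile()), "no such file")
})

test_that("read_coco accepts empty annotation arrays", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(images = list(list(id = 1, file_name = "x.png",
                                               width = 10, height = 10)),
                            annotations = list(),
                            categories = list(list(id = 1, name = "fruit"))),
                       path, auto_unbox = TRUE)
  ds <- read_coco(path)
  expect_equal(nrow(ds$annotations), 0)
})

test_that("read_coco names unknown image ids", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = list(list(id = 1, file_name = "x.png", width = 10, height = 10)),
    annotations = list(list(id = 1, image_id = 99, category_id = 1,
                            bbox = c(1, 1, 2, 2))),
    categories = list(list(id = 1, name = "fruit"))), path, auto_unbox = TRUE)
  expect_error(read_coco(path), "99")
})

test_that("COCO round-trip preserves boxes and ids", {
  path <- write_tiny_coco(tempfile(fileext = ".json"))
  ds <- read_coco(path)
  out <- tempfile(fileext = ".json")
  write_coco(ds, out)
  ds2 <- read_coco(out)
  expect_equal(ds2$images, ds$images)
  expect_equal(ds2$annotations$ann_id, ds$annotations$ann_id)
  expect_equal(as.matrix(ds2$annotations[, c("x_min", "y_min", "x_max", "y_max")]),
               as.matrix(ds$annotations[, c("x_min", "y_min", "x_max", "y_max")]),
               tolerance = 1e-6)
})

test_that("convert_labelme produces tight bounds and deterministic ids", {
  dir <- write_labelme_dir(tempfile())
  ds <- convert_labelme(dir)
  expect_equal(nrow(ds$images), 2)
  expect_equal(nrow(ds$annotations), 3)
  # rectangle (5,5)-(15,25) -> bbox [5,5,10,20]
  r <- ds$annotations[1, ]
  expect_equal(c(r$x_min, r$y_min, r$x_max, r$y_max), c(5, 5, 15, 25))
  # polygon (0,0),(4,0),(2,6) -> bound (0,0,4,6)
  p <- ds$annotations[2, ]
  expect_equal(c(p$x_min, p$y_min, p$x_max, p$y_max), c(0, 0, 4, 6))
  # deterministic across runs: byte-compare serialized output
  f1 <- tempfile(); f2 <- tempfile()
  write_coco(convert_labelme(dir), f1)
  write_coco(convert_labelme(dir), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degenerate LabelMe shapes are skipped with a warning", {
  dir <- tempfile(); dir.create(dir)
  jsonlite::write_json(list(imagePath = "z.png", imageWidth = 10L,
                            imageHeight = 10L,
                            shapes = list(list(label = "fruit",
                                               points = list(c(1, 1))))),
                       file.path(dir, "z.json"), auto_unbox = TRUE)
  expect_warning(ds <- convert_labelme(dir), "skipped")
  expect_equal(nrow(ds$annotations), 0)
  expect_equal(attr(ds, "skipped"), 1L)
})

test_that("split sizes follow round-half-up of ratio * N", {
  ns <- asNamespace("fcoslsc")
  # the reference apple dataset arithmetic: 1361 at 7:3 -> 953 / 408
  expect_equal(ns$round_half_up(0.7 * 1361), 953)
  imgs <- tibble::tibble(image_id = 1:1361, file_name = "x", width = 1L,
                         height = 1L)
  ds <- ns$new_coco_dataset(imgs, ns$empty_annotations(),
                            tibble::tibble(category_id = 1L, name = "fruit"))
  sp <- split_dataset(ds, 0.7, seed = 3)
  expect_equal(nrow(sp$train$images), 953)
  expect_equal(nrow(sp$val$images), 408)
  # N = 10 -> 7 / 3
  ds10 <- ns$new_coco_dataset(imgs[1:10, ], ns$empty_annotations(),
                              ds$categories)
  sp10 <- split_dataset(ds10, 0.7, seed = 1)
  expect_equal(nrow(sp10$train$images), 7)
  # rounding rule for every N in 2..1000
  for (n in 2:1000) {
    k <- ns$round_half_up(0.7 * n)
    expect_identical(k, floor(0.7 * n + 0.5))
    expect_true(k >= 1 && k <= n)
  }
})

test_that("split is a seeded deterministic partition", {
  ns <- asNamespace("fcoslsc")
  imgs <- tibble::tibble(image_id = 1:57, file_name = "x", width = 1L,
                         height = 1L)
  ds <- ns$new_coco_dataset(imgs, ns$empty_annotations(),
                            tibble::tibble(category_id = 1L, name = "f"))
  s1 <- split_dataset(ds, 0.7, seed = 11)
  s2 <- split_dataset(ds, 0.7, seed = 11)
  expect_identical(s1$train$images$image_id, s2$train$images$image_id)
  expect_length(intersect(s1$train$images$image_id,
                          s1$val$images$image_id), 0)
  expect_equal(sort(c(s1$train$images$image_id, s1$val$images$image_id)), 1:57)
  s3 <- split_dataset(ds, 0.7, seed = 12)
  expect_false(identical(s1$train$images$image_id, s3$train$images$image_id))
  expect_error(split_dataset(ns$new_coco_dataset(imgs[1, ],
    ns$empty_annotations(), ds$categories)), "at least 2")
})

test_that("preprocessing resizes, flips, normalizes and pads as specified", {
  set.seed(5)
  img <- array(runif(40 * 60 * 3), c(40, 60, 3))  # H=40, W=60
  boxes <- tibble::tibble(x_min = 6, y_min = 4, x_max = 30, y_max = 20,
                          category_id = 1L)
  # resize 60x40 -> 600x400 scales boxes by 10
  pp <- preprocess_sample(list(image = img, boxes = boxes),
                          train_mode = FALSE, target_size = c(600, 400))
  expect_equal(pp$boxes$x_min, 60)
  expect_equal(pp$boxes$y_max, 200)
  # 600x400 pads to 608x416 (next multiples of 32)
  expect_equal(unname(pp$padded_size), c(608, 416))
  expect_equal(dim(pp$image), c(416, 608, 3))
  # padding changes neither coordinates nor pairwise IoU
  expect_equal(unname(pp$ops$pad), c(8, 16))
  # normalization: padded region is exactly zero, image region is centered
  expect_true(all(pp$image[401:416, , ] == 0))
  # flip determinism and correctness under a seed that flips
  flipped <- NULL
  for (s in 1:20) {
    t1 <- preprocess_sample(list(image = img, boxes = boxes), train_mode = TRUE,
                            target_size = c(60, 40), seed = s)
    t2 <- preprocess_sample(list(image = img, boxes = boxes), train_mode = TRUE,
                            target_size = c(60, 40), seed = s)
    expect_identical(t1$ops$flip, t2$ops$flip)
    if (t1$ops$flip) flipped <- t1
  }
  expect_false(is.null(flipped))
  expect_equal(flipped$boxes$x_min, 60 - 30)
  expect_equal(flipped$boxes$x_max, 60 - 6)
})
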