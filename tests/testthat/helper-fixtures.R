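# Shared fixtures, built in code at test time.

ns <- asNamespace("fcoslsc")

# a hand-authored 3-image / 5-annotation COCO file
write_tiny_coco <- function(path) {
  doc <- list(
    images = list(
      list(id = 1L, file_name = "a.png", width = 100L, height = 80L),
      list(id = 2L, file_name = "b.png", width = 64L, height = 64L),
      list(id = 3L, file_name = "c.png", width = 120L, height = 90L)
    ),
    annotations = list(
      list(id = 1L, image_id = 1L, category_id = 1L, bbox = c(10, 20, 30, 40)),
      list(id = 2L, image_id = 1L, category_id = 1L, bbox = c(5, 5, 10, 10)),
      list(id = 3L, image_id = 2L, category_id = 2L, bbox = c(0, 0, 32, 16)),
      list(id = 4L, image_id = 3L, category_id = 1L, bbox = c(50, 30, 20, 25)),
      list(id = 5L, image_id = 3L, category_id = 2L, bbox = c(1, 2, 3, 4.5))
    ),
    categories = list(
      list(id = 1L, name = "apple"),
      list(id = 2L, name = "persimmon")
    )
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  path
}

write_labelme_dir <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- list(imagePath = "scene1.png", imageWidth = 100L, imageHeight = 80L,
            shapes = list(
              list(label = "fruit", shape_type = "rectangle",
                   points = list(c(5, 5), c(15, 25))),
              list(label = "fruit", shape_type = "polygon",
                   points = list(c(0, 0), c(4, 0), c(2, 6)))))
  b <- list(imagePath = "scene2.png", imageWidth = 60L, imageHeight = 60L,
            shapes = list(
              list(label = "leaf", shape_type = "polygon",
                   points = list(c(10, 10), c(20, 12), c(18, 30), c(9, 22)))))
  jsonlite::write_json(a, file.path(dir, "scene1.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(b, file.path(dir, "scene2.json"), auto_unbox = TRUE,
                       digits = NA)
  dir
}

# small easy scene config used across tests
easy_scene_config <- function(seed = 100L, ...) {
  scene_config(image_size = c(128, 128), fruit_count_range = c(1, 3),
               fruit_radius_range = c(12, 28), fruit_hue_offset = 40,
               occluder_count_range = c(0, 0), overlap_probability = 0,
               blur_sigma_range = c(0, 0.5), seed = seed, ...)
}

tiny_model_config <- function(...) {
  detector_config(width_mult = 0.25, fpn_channels = 32L, lsc_blocks = 1L, ...)
}

# finite-difference gradient of scalar-valued fn at selected indices
fd_grad <- function(fn, x, idx, eps = 1e-5) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (fn(xp) - fn(xm)) / (2 * eps)
  }, numeric(1))
}
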