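test_that("make_shape is seeded, simple, and a circle at zero amplitudes", {
  cls <- default_shape_classes()[[1]]
  a <- make_shape(cls, 20, seed = 5)
  b <- make_shape(cls, 20, seed = 5)
  expect_identical(unclass(a), unclass(b))
  expect_true(contourseg:::contour_is_simple(resample_contour(a, 64)))
  # zero harmonics: a circle of the base radius with extremes at +-radius
  circ_cls <- cls
  circ_cls$amp_range <- c(0, 0); circ_cls$amp2 <- 0
  ct <- make_shape(circ_cls, 15, seed = 2)
  # the aspect stretch is area-preserving, so the area stays pi * radius^2
  expect_equal(polygon_area(ct), pi * 15^2, tolerance = 1e-2)
  ex <- contour_extremes(ct)
  expect_lte(ex$top[2], ex$bottom[2])
  expect_lte(ex$leftmost[1], ex$rightmost[1])
  expect_error(make_shape(cls, -3, seed = 1), "parameter")
  # generated contours are simple per the O(n^2) segment-intersection check
  set.seed(8)
  for (i in 1:10) {
    cls_i <- default_shape_classes()[[sample(12, 1)]]
    ct_i <- make_shape(cls_i, runif(1, 8, 25), seed = sample(1e6, 1))
    expect_true(contourseg:::contour_is_simple(resample_contour(ct_i, 48)))
  }
})

test_that("render_scene produces consistent ground truth", {
  inst <- data.frame(class_id = 1L, cx = 64, cy = 64, scale = 20,
                     shape_seed = 7)
  sc <- render_scene(scene_spec(128L, 128L, inst), seed = 3)
  expect_equal(dim(sc$image), c(128, 128, 3))
  expect_length(sc$annotations, 1)
  a <- sc$annotations[[1]]
  # box equals the polygon's tight bounding rectangle
  expect_equal(as.numeric(a$bbox),
               as.numeric(contour_bbox(a$polygon)), tolerance = 1e-9)
  # untruncated: polygon well inside the frame
  expect_true(all(a$polygon[, 1] > 0 & a$polygon[, 1] < 128))
  # truncation: an instance centered on the border is clipped, box touches it
  inst_t <- data.frame(class_id = 2L, cx = 2, cy = 64, scale = 18,
                       shape_seed = 9)
  sct <- render_scene(scene_spec(128L, 128L, inst_t), seed = 4)
  at <- sct$annotations[[1]]
  expect_equal(as.numeric(at$bbox)[1], 0)
  expect_true(all(at$polygon[, 1] >= 0))
  # fully outside is a spec error
  inst_o <- data.frame(class_id = 1L, cx = -90, cy = -90, scale = 10,
                       shape_seed = 1)
  expect_error(render_scene(scene_spec(128L, 128L, inst_o), seed = 1),
               "spec")
})

test_that("occluded instances lose visible area to instances in front", {
  inst <- data.frame(class_id = c(1L, 1L), cx = c(60, 70), cy = c(64, 64),
                     scale = c(18, 18), shape_seed = c(3, 4))
  sc <- render_scene(scene_spec(128L, 128L, inst,
                                regimes = list(small = FALSE, overlap = TRUE,
                                               camouflage = FALSE,
                                               truncation = FALSE)),
                     seed = 6)
  a1 <- sc$annotations[[1]]   # behind
  a2 <- sc$annotations[[2]]   # in front
  full1 <- sum(contour_to_mask(a1$polygon, 128, 128))
  expect_lt(a1$visible_area, full1)
  expect_equal(a2$visible_area, sum(contour_to_mask(a2$polygon, 128, 128)))
})

test_that("generate_dataset is balanced, split-stratified and seed-reproducible", {
  ds <- generate_dataset(n_classes = 3L, images_per_class = 10L, seed = 9,
                         keep_images = FALSE)
  expect_length(ds$images, 30)
  m <- ds$manifest
  expect_equal(m$images, rep(10L, 3))
  tot <- manifest_summary(m)
  expect_equal(tot$images, 30)
  expect_equal(tot$training_instances + tot$validation_instances,
               length(ds$annotations))
  # 0.85 split: ceil/round to 8 train + 2 val per class at 10 images
  for (cl in 1:3) {
    expect_length(contourseg:::dataset_image_ids(ds, "train", cl), 8)
    expect_length(contourseg:::dataset_image_ids(ds, "val", cl), 2)
  }
  # annotation box equals the tight box of its polygon
  for (a in ds$annotations[seq(1, length(ds$annotations), by = 7)]) {
    p <- contourseg:::annotation_polygon(a)
    expect_equal(as.numeric(contourseg:::annotation_bbox(a)),
                 as.numeric(contour_bbox(p)), tolerance = 0.02)
  }
  ds2 <- generate_dataset(n_classes = 3L, images_per_class = 10L, seed = 9,
                          keep_images = FALSE)
  expect_identical(jsonlite::toJSON(ds$annotations, auto_unbox = TRUE),
                   jsonlite::toJSON(ds2$annotations, auto_unbox = TRUE))
})

test_that("85/15 split arithmetic matches at 100 images per class", {
  ds <- generate_dataset(n_classes = 2L, images_per_class = 100L,
                         seed = 4, keep_images = FALSE)
  for (cl in 1:2) {
    expect_length(contourseg:::dataset_image_ids(ds, "train", cl), 85)
    expect_length(contourseg:::dataset_image_ids(ds, "val", cl), 15)
  }
})

test_that("manifest_summary reproduces printed dataset-composition totals", {
  rows <- utils::read.csv(system.file("extdata", "mammal_manifest.csv",
                                      package = "contourseg"))
  tot <- manifest_summary(rows)
  expect_identical(tot$images, 4884L)
  expect_identical(tot$training_instances, 5883L)
  expect_identical(tot$validation_instances, 994L)
  zero <- rows; zero$images <- 0L
  zero$training_instances <- 0L; zero$validation_instances <- 0L
  z <- manifest_summary(zero)
  expect_identical(z$images + z$training_instances +
                     z$validation_instances, 0L)
  bad <- rows; bad$images[1] <- -1L
  expect_error(manifest_summary(bad), "data")
})

test_that("COCO disk round trip preserves annotations and images", {
  ds <- generate_dataset(n_classes = 2L, images_per_class = 3L, seed = 2)
  dir <- file.path(tempdir(), "cocotest")
  write_coco(ds, dir)
  expect_true(file.exists(file.path(dir, "annotations.json")))
  back <- read_coco(dir)
  expect_length(back$images, length(ds$images))
  expect_length(back$annotations, length(ds$annotations))
  a0 <- ds$annotations[[1]]; a1 <- back$annotations[[1]]
  expect_equal(a1$bbox, round(a0$bbox, 2), tolerance = 1e-9)
  expect_equal(a1$category_id, a0$category_id)
  im0 <- ds$images[[1]]$array
  im1 <- back$images[[1]]$array
  expect_equal(dim(im1), dim(im0))
  expect_lt(max(abs(im1 - im0)), 1 / 255)
  unlink(dir, recursive = TRUE)
})

test_that("classes are separable by radial signature (> 90% nearest-centroid)", {
  classes <- default_shape_classes()
  set.seed(77)
  sigs <- list(); labs <- integer(0)
  for (cl in seq_along(classes)) {
    for (r in 1:12) {
      ct <- make_shape(classes[[cl]], 20, seed = cl * 1000 + r)
      sigs[[length(sigs) + 1L]] <- radial_signature(ct)
      labs <- c(labs, cl)
    }
  }
  S <- do.call(rbind, sigs)
  idx_train <- which(seq_along(labs) %% 2 == 1)
  idx_test <- which(seq_along(labs) %% 2 == 0)
  pred <- classify_by_signature(S[idx_train, ], labs[idx_train],
                                S[idx_test, ])
  acc <- mean(pred == labs[idx_test])
  expect_gt(acc, 0.9)
})
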