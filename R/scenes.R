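#' @title Synthetic scene generation
#' @description Seeded renderer of pseudo-animal scenes with COCO-style
#'   ground truth. Emulates the structure of a balanced camera-trap dataset
#'   (about 12 classes, a configurable number of images per class, an 0.85
#'   train/eval split) and its four challenge regimes: multiple small
#'   targets, overlapping bodies, camouflaged backgrounds, and bodies
#'   truncated by the image border.
#' @name scenes
NULL

#' Default challenge-regime probabilities
#'
#' Per-scene probabilities of the four challenge regimes: multiple small
#' targets, overlapping bodies, camouflaged backgrounds, truncated bodies.
#' @return Named list of probabilities.
#' @export
default_regimes <- function() {
  list(small = 0.15, overlap = 0.15, camouflage = 0.15, truncation = 0.15)
}

# Low-frequency noise field: coarse Gaussian grid bilinearly upsampled.
smooth_noise <- function(H, W, cells = 8L, sd = 1) {
  g <- matrix(stats::rnorm((cells + 1)^2, sd = sd), cells + 1, cells + 1)
  ry <- (seq_len(H) - 0.5) / H * cells
  rx <- (seq_len(W) - 0.5) / W * cells
  i0 <- pmin(floor(ry), cells - 1); ty <- ry - i0
  j0 <- pmin(floor(rx), cells - 1); tx <- rx - j0
  A <- g[cbind(rep(i0 + 1, W), rep(j0 + 1, each = H))]
  B <- g[cbind(rep(i0 + 2, W), rep(j0 + 1, each = H))]
  C <- g[cbind(rep(i0 + 1, W), rep(j0 + 2, each = H))]
  D <- g[cbind(rep(i0 + 2, W), rep(j0 + 2, each = H))]
  ty <- rep(ty, W); tx <- rep(tx, each = H)
  v <- A * (1 - ty) * (1 - tx) + B * ty * (1 - tx) +
    C * (1 - ty) * tx + D * ty * tx
  matrix(v, H, W)
}

#' Specify a synthetic scene
#'
#' @param width,height Image size in pixels.
#' @param instances Data frame with one row per instance: `class_id`, `cx`,
#'   `cy` (center), `scale` (base radius, pixels), `shape_seed`.
#' @param regimes Named logical list: `small`, `overlap`, `camouflage`,
#'   `truncation` (flags recorded with the scene; `camouflage` changes
#'   rendering, the others are realized through the instance layout).
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(width = 128L, height = 128L, instances,
                       regimes = list(small = FALSE, overlap = FALSE,
                                      camouflage = FALSE, truncation = FALSE)) {
  if (nrow(instances) < 1L) stop("parameter: at least one instance required")
  structure(list(width = as.integer(width), height = as.integer(height),
                 instances = instances, regimes = regimes),
            class = "scene_spec")
}

#' Render a scene to an image plus COCO-style annotations
#'
#' Instances are composited back-to-front, so later instances occlude
#' earlier ones. Under the camouflage regime the body color is drawn from
#' the background color with only a small contrast offset. Contours crossing
#' the image border are clipped (polygon and box), emulating truncated
#' bodies. An instance entirely outside the frame is an error.
#'
#' Each annotation carries the instance outline clipped to the image
#' (`polygon`), its tight box, the rasterized visible pixel area after
#' occlusion (`visible_area`) and the full outline area.
#' @param spec A [scene_spec()].
#' @param seed Integer seed (textures and per-instance appearance).
#' @param classes Shape-class list, [default_shape_classes()].
#' @return List `(image, annotations, spec)`; `image` is an
#'   `[H, W, 3]` array in `[0, 1]`.
#' @export
render_scene <- function(spec, seed, classes = default_shape_classes()) {
  H <- spec$height; W <- spec$width
  set.seed(as.integer(seed))
  img_rect <- bbox(0, 0, W, H)

  # background: earthy base color + low-frequency texture + grain
  bg_col <- c(stats::runif(1, 0.25, 0.5), stats::runif(1, 0.3, 0.5),
              stats::runif(1, 0.15, 0.35))
  field <- smooth_noise(H, W, cells = 8L, sd = 0.08)
  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    img[, , ch] <- bg_col[ch] + field + stats::rnorm(H * W, sd = 0.02)
  }

  camo <- isTRUE(spec$regimes$camouflage)
  anns <- list()
  masks <- list()
  n_inst <- nrow(spec$instances)
  for (i in seq_len(n_inst)) {
    inst <- spec$instances[i, ]
    cls <- classes[[inst$class_id]]
    sh <- make_shape(cls, inst$scale, inst$shape_seed)
    ct <- contour(sweep(unclass(sh), 2, c(inst$cx, inst$cy), `+`))
    clipped <- clip_polygon(ct, img_rect)
    if (is.null(clipped)) {
      stop("spec: instance entirely outside the image frame")
    }
    mask <- contour_to_mask(clipped, H, W)
    base_col <- if (camo) {
      bg_col + stats::runif(3, -0.06, 0.06) + 0.05
    } else {
      cls$color
    }
    tex <- smooth_noise(H, W, cells = 10L, sd = cls$noise_scale)
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[mask] <- base_col[ch] + tex[mask] +
        stats::rnorm(sum(mask), sd = 0.015)
      img[, , ch] <- layer
    }
    masks[[i]] <- mask
    anns[[i]] <- list(
      category_id = cls$id,
      polygon = clipped,
      bbox = contour_bbox(clipped),
      area = polygon_area(clipped),
      iscrowd = 0L
    )
  }
  # visible pixel areas after occlusion by later (front) instances
  for (i in seq_len(n_inst)) {
    vis <- masks[[i]]
    if (i < n_inst) for (j in (i + 1):n_inst) vis <- vis & !masks[[j]]
    anns[[i]]$visible_area <- sum(vis)
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  list(image = img, annotations = anns, spec = spec)
}

# Draw a scene layout for one image of class `class_id` under sampled
# regime flags. Returns a scene_spec.
sample_scene_spec <- function(class_id, width, height, regimes_prob, rng_seed) {
  set.seed(as.integer(rng_seed))
  flags <- lapply(regimes_prob, function(p) stats::runif(1) < p)
  small <- isTRUE(flags$small); overl <- isTRUE(flags$overlap)
  trunc <- isTRUE(flags$truncation)
  scale_range <- if (small) c(7, 11) else c(14, 26)
  n_inst <- if (small) 2L + stats::rpois(1, 0.8) else 1L + stats::rpois(1, 0.4)
  n_inst <- min(n_inst, 4L)
  if (overl && n_inst < 2L) n_inst <- 2L
  rows <- vector("list", n_inst)
  for (k in seq_len(n_inst)) {
    sc <- stats::runif(1, scale_range[1], scale_range[2])
    margin <- sc * 1.45
    if (trunc && k == 1L) {
      # center close enough to a border that the body crosses it
      side <- sample(4L, 1L)
      off <- stats::runif(1, -0.3 * sc, 0.3 * sc)
      pos_along <- stats::runif(1, margin, width - margin)
      cx <- switch(side, off, width - off, pos_along, pos_along)
      cy <- switch(side, stats::runif(1, margin, height - margin),
                   stats::runif(1, margin, height - margin), off, height - off)
    } else if (overl && k == 2L) {
      prev <- rows[[1]]
      ang <- stats::runif(1, 0, 2 * pi)
      dst <- stats::runif(1, 0.6, 0.9) * (prev$scale + sc) / 2
      cx <- min(max(prev$cx + dst * cos(ang), margin), width - margin)
      cy <- min(max(prev$cy + dst * sin(ang), margin), height - margin)
    } else {
      cx <- stats::runif(1, margin, width - margin)
      cy <- stats::runif(1, margin, height - margin)
    }
    rows[[k]] <- data.frame(class_id = class_id, cx = cx, cy = cy,
                            scale = sc, shape_seed = stats::runif(1) * 1e7)
  }
  scene_spec(width, height, do.call(rbind, rows),
             regimes = lapply(flags, isTRUE))
}

#' Generate a full synthetic dataset with COCO-style ground truth
#'
#' Scenes are single-species (all instances in an image share the class,
#' as is typical of camera-trap frames); per-class image counts are
#' balanced; a stratified train/validation split is drawn at `split_ratio`.
#' Fully reproducible from `seed`.
#' @param n_classes Number of shape classes (default 12).
#' @param images_per_class Images per class (default 40).
#' @param split_ratio Fraction of images per class assigned to training
#'   (default 0.85).
#' @param regimes Named list of challenge-regime probabilities
#'   (see [default_regimes()]).
#' @param seed Integer master seed.
#' @param image_size Square image side in pixels (default 128).
#' @param dir Optional directory; when given, PNG images and an
#'   `annotations.json` in COCO layout are written there.
#' @param keep_images Keep rendered arrays in memory (default TRUE).
#' @return A `coco_dataset` list: `images`, `annotations`, `categories`,
#'   `manifest` (per-class data frame) and `classes`.
#' @export
generate_dataset <- function(n_classes = 12L, images_per_class = 40L,
                             split_ratio = 0.85, regimes = default_regimes(),
                             seed = 1L, image_size = 128L, dir = NULL,
                             keep_images = TRUE) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("parameter: n_classes must be >= 2")
  classes <- default_shape_classes(n_classes)
  images <- list(); annotations <- list()
  ann_id <- 0L; img_id <- 0L
  n_train <- as.integer(round(split_ratio * images_per_class))
  for (c in seq_len(n_classes)) {
    for (j in seq_len(images_per_class)) {
      img_id <- img_id + 1L
      sseed <- (as.integer(seed) * 131L + c * 10007L + j * 97L) %% 2100000000L
      sp <- sample_scene_spec(c, image_size, image_size,
                              regimes, sseed)
      sc <- render_scene(sp, sseed + 1L, classes)
      split <- if (j <= n_train) "train" else "val"
      images[[img_id]] <- list(
        id = img_id, file_name = sprintf("img_%05d.png", img_id),
        height = image_size, width = image_size, split = split,
        class_id = c, regimes = sp$regimes,
        array = if (keep_images) sc$image else NULL
      )
      for (a in sc$annotations) {
        ann_id <- ann_id + 1L
        annotations[[ann_id]] <- list(
          id = ann_id, image_id = img_id, category_id = a$category_id,
          bbox = bbox_to_xywh(a$bbox),
          segmentation = list(round(contour_to_coco(a$polygon), 2)),
          area = round(a$area, 2), visible_area = a$visible_area,
          iscrowd = 0L, split = split
        )
      }
    }
  }
  manifest <- dataset_manifest(images, annotations, n_classes, split_ratio)
  ds <- structure(list(
    images = images, annotations = annotations,
    categories = lapply(classes, function(cl) list(id = cl$id, name = cl$name)),
    classes = classes, manifest = manifest, image_size = image_size,
    split_ratio = split_ratio, seed = as.integer(seed)
  ), class = "coco_dataset")
  if (!is.null(dir)) write_coco(ds, dir)
  ds
}

dataset_manifest <- function(images, annotations, n_classes, split_ratio) {
  rows <- data.frame(class_id = seq_len(n_classes),
                     images = 0L, training_instances = 0L,
                     validation_instances = 0L)
  for (im in images) rows$images[im$class_id] <- rows$images[im$class_id] + 1L
  for (a in annotations) {
    col <- if (a$split == "train") "training_instances" else
      "validation_instances"
    rows[[col]][a$category_id] <- rows[[col]][a$category_id] + 1L
  }
  attr(rows, "split_ratio") <- split_ratio
  rows
}

#' Column totals of a dataset manifest
#'
#' Sums the per-class image and instance counts of a manifest table (the
#' same arithmetic as the Total row of a dataset composition table).
#' @param per_class_rows Data frame with columns `images`,
#'   `training_instances`, `validation_instances` (one row per class).
#' @return Named list of totals.
#' @export
manifest_summary <- function(per_class_rows) {
  cols <- c("images", "training_instances", "validation_instances")
  if (!all(cols %in% names(per_class_rows))) {
    stop("data: manifest must have images/training_instances/validation_instances columns")
  }
  vals <- unlist(per_class_rows[cols])
  if (any(vals < 0) || any(vals != floor(vals))) {
    stop("data: manifest counts must be non-negative integers")
  }
  list(images = sum(per_class_rows$images),
       training_instances = sum(per_class_rows$training_instances),
       validation_instances = sum(per_class_rows$validation_instances))
}

#' @export
print.coco_dataset <- function(x, ...) {
  cat(sprintf("<coco_dataset: %d images, %d annotations, %d classes>\n",
              length(x$images), length(x$annotations), length(x$categories)))
  invisible(x)
}

# Convenience accessors -----------------------------------------------------

dataset_image_ids <- function(ds, split = NULL, class_id = NULL) {
  keep <- vapply(ds$images, function(im) {
    (is.null(split) || im$split == split) &&
      (is.null(class_id) || im$class_id %in% class_id)
  }, logical(1))
  vapply(ds$images[keep], `[[`, integer(1), "id")
}

dataset_annotations_for <- function(ds, image_id) {
  Filter(function(a) a$image_id == image_id, ds$annotations)
}

dataset_image <- function(ds, image_id) {
  for (im in ds$images) if (im$id == image_id) return(im)
  stop("data: unknown image id")
}
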