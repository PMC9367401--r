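#' @title Pipeline orchestration
#' @description Ties the stages together: detection (or oracle boxes) feeds
#'   the contour approximation (diamond, extreme points, octagon, iterative
#'   deformation), and the n-shot study loops fine-tuning and evaluation
#'   over a grid of shot levels.
#' @name pipeline
NULL

#' Default run configuration
#'
#' Collects every tunable of the pipeline with its default: SGD momentum
#' 0.9, weight decay 0.0001, learning rates 0.02 (base) / 0.001
#' (fine-tune), batch size 2, 40 diamond points, N = 128 contour points,
#' 3 deformation iterations, 3:1 base:novel class split, 0.85 train ratio,
#' and the shot grid 1, 2, 3, 5, 10, 30.
#' @param seed Master seed.
#' @param n_classes,images_per_class,image_size Synthetic dataset scale.
#' @param shot_grid n-shot levels for the study.
#' @return A `run_config` list with `snake` ([snake_config()]), `train`
#'   ([train_config()]), `detector` ([detector_config()]), dataset settings
#'   and the shot grid.
#' @export
run_config <- function(seed = 1L, n_classes = 12L, images_per_class = 40L,
                       image_size = 128L,
                       shot_grid = c(1L, 2L, 3L, 5L, 10L, 30L)) {
  structure(list(
    seed = as.integer(seed),
    snake = snake_config(),
    train = train_config(seed = seed),
    detector = detector_config(),
    split_ratio = 0.85,
    base_novel_ratio = 3,
    n_classes = as.integer(n_classes),
    images_per_class = as.integer(images_per_class),
    image_size = as.integer(image_size),
    regimes = default_regimes(),
    shot_grid = as.integer(shot_grid)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_run_config`: a `run_config`; `write_run_config`: `path`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config(seed = y$seed %||% 1L)
  for (nm in names(y)) {
    if (nm %in% c("snake", "train", "detector")) {
      for (k in names(y[[nm]])) cfg[[nm]][[k]] <- y[[nm]][[k]]
    } else {
      cfg[[nm]] <- y[[nm]]
    }
  }
  cfg
}

#' Run the full two-stage pipeline on one image
#'
#' detect -> diamond -> extreme points -> octagon -> iterative deformation,
#' per detection. In oracle mode the ground-truth annotations stand in for
#' the detector (score 1, IoU 1 with the annotation boxes).
#' @param image `[H, W, 3]` array.
#' @param detector_model A trained `fsod_model`, or `NULL` in oracle mode.
#' @param snake_model A trained `snake_model`.
#' @param oracle_annotations Annotation list for oracle-detector mode.
#' @param score_threshold,nms_iou Detector post-processing settings.
#' @return List of instances: `box`, `category_id`, `score`, `contour`.
#' @export
run_full_pipeline <- function(image, detector_model, snake_model,
                              oracle_annotations = NULL,
                              score_threshold = 0.5, nms_iou = 0.5) {
  if (is.null(detector_model) && is.null(oracle_annotations)) {
    stop("state: need a trained detector or oracle annotations")
  }
  dets <- if (!is.null(oracle_annotations)) {
    lapply(oracle_annotations, function(a)
      list(box = annotation_bbox(a), category_id = a$category_id,
           score = 1.0))
  } else {
    detect(detector_model, image, score_threshold = score_threshold,
           nms_iou = nms_iou)
  }
  if (length(dets) == 0L) return(list())
  fg <- snake_features(snake_model, image)
  H <- dim(image)[1]; W <- dim(image)[2]
  lapply(dets, function(d) {
    b <- as_bbox(d$box)
    # keep the box inside the feature grid
    b <- bbox(max(b[1], 0), max(b[2], 0), min(b[3], W), min(b[4], H))
    d$contour <- snake_segment(snake_model, b, fg)
    d
  })
}

# Frozen-extractor evaluation caches for a split (reusable across any
# fine-tuned predictor sharing the extractor).
build_eval_caches <- function(model, dataset, split = "val") {
  ids <- dataset_image_ids(dataset, split = split)
  caches <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    im <- dataset_image(dataset, ids[i])
    caches[[i]] <- detector_image_cache(model, im$array)
    caches[[i]]$image_id <- ids[i]
  }
  caches
}

predictions_from_caches <- function(model, caches, score_threshold = 0.05,
                                    nms_iou = 0.5) {
  preds <- list()
  for (ch in caches) {
    dets <- detect_from_cache(model, ch, score_threshold, nms_iou)
    for (d in dets) {
      d$image_id <- ch$image_id
      preds[[length(preds) + 1L]] <- d
    }
  }
  preds
}

#' Run the n-shot fine-tuning study
#'
#' Base-trains the detector on the base classes, then for every shot level
#' of the grid fine-tunes on a balanced n-shot subset and evaluates box
#' AP/AP50/AP75 separately over novel and base classes on the validation
#' split, averaging over `n_seeds` fine-tuning seeds (novel-row
#' initialization, subset draw, SGD sampling). The frozen extractor's
#' validation features are computed once and shared by every fine-tuned
#' model.
#' @param dataset A `coco_dataset` (in-memory images).
#' @param cfg A [run_config()].
#' @param n_seeds Fine-tuning seeds per shot level (default 3).
#' @param base_model Optional pre-base-trained model to reuse.
#' @param progress Print progress lines to stderr.
#' @return List: `table` (data frame: shot, seed, group, AP, AP50, AP75),
#'   `summary` (data frame: shot, group, mean AP50 over seeds),
#'   `base_model`, `split`, and the per-run fine-tune `curves`.
#' @export
run_nshot_study <- function(dataset, cfg = run_config(), n_seeds = 3L,
                            base_model = NULL, progress = FALSE) {
  split <- split_base_novel(dataset$categories, ratio = cfg$base_novel_ratio,
                            seed = cfg$seed)
  max_shot <- max(cfg$shot_grid)
  for (cl in c(split$base_classes, split$novel_classes)) {
    n_avail <- length(dataset_image_ids(dataset, "train", cl))
    if (n_avail < max_shot) {
      stop(sprintf("data: class %d has %d training images, fewer than the largest shot level %d",
                   cl, n_avail, max_shot))
    }
  }
  if (is.null(base_model)) {
    base_ids <- dataset_image_ids(dataset, "train", split$base_classes)
    base_ds <- subset_dataset(dataset, base_ids)
    model0 <- fsod_init(split$base_classes, cfg$detector, seed = cfg$seed)
    if (progress) message("base training on ", length(base_ids), " images")
    base_model <- base_train(model0, base_ds, cfg$train)
  }
  if (progress) message("building frozen evaluation caches")
  caches <- build_eval_caches(base_model, dataset, split = "val")
  rows <- list(); curves <- list()
  for (shot in cfg$shot_grid) {
    for (sd in seq_len(n_seeds)) {
      tc <- cfg$train
      tc$n_shot <- shot
      tc$seed <- cfg$seed + 1000L * sd + shot
      subset <- build_nshot_subset(dataset, split, shot, seed = tc$seed)
      ft <- fine_tune(base_model, subset, split, tc)
      preds <- predictions_from_caches(ft, caches)
      for (group in c("novel", "base")) {
        cls <- if (group == "novel") split$novel_classes else
          split$base_classes
        ev <- evaluate_run(preds, dataset, mode = "box", split = "val",
                           class_ids = cls)
        rows[[length(rows) + 1L]] <- data.frame(
          shot = shot, seed = sd, group = group,
          AP = ev$AP, AP50 = ev$AP50, AP75 = ev$AP75)
      }
      curves[[sprintf("shot%d_seed%d", shot, sd)]] <- ft$finetune_curve
      if (progress) {
        message(sprintf("shot %d seed %d done", shot, sd))
      }
    }
  }
  table <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(AP, AP50, AP75) ~ shot + group,
                              data = table, FUN = mean)
  summary <- summary[order(summary$group, summary$shot), ]
  list(table = table, summary = summary, base_model = base_model,
       split = split, curves = curves)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seeds and package version so a run can be
#' repeated bit-comparably.
#' @param cfg A `run_config`.
#' @param path Output JSON path.
#' @export
write_run_manifest <- function(cfg, path) {
  m <- list(
    config = lapply(unclass(cfg), function(x)
      if (is.list(x)) unclass(x) else x),
    package_version = as.character(utils::packageVersion("contourseg")),
    r_version = R.version.string,
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                      collapse = "")))
  )
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
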