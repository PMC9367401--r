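#' @title Snake training and held-out evaluation
#' @description Supervised training of the contour deformer on synthetic
#'   scenes with exact polygon ground truth. Boxes come from the annotations
#'   (oracle-detector mode) with a small random jitter so the deformer is
#'   robust to imperfect detections. The extreme-point block is supervised
#'   by the analytic extreme points; each deformation iteration is
#'   supervised by the ground-truth contour (resampled to N vertices,
#'   nearest-start alignment), with the contour detached between iterations
#'   so offsets are regressed per round.
#' @name snake_train
NULL

# Supervised offsets at the 4 diamond anchors + per-iteration contour
# offsets; backprop through both snake blocks and the feature extractor.
snake_image_step <- function(model, img, anns, jitter = 1.5) {
  cfg <- model$cfg
  H <- dim(img)[1]; W <- dim(img)[2]
  arch <- snake_arch(cfg)
  bb <- conv_stack_forward(model$feat, image_to_matrix(img), arch, H, W)
  fg <- structure(list(levels = snake_levels_from_cache(bb)),
                  class = "snake_features")
  d_grids <- lapply(fg$levels, function(lv) lv$grid * 0)
  ex_g <- NULL; de_g <- NULL
  total <- 0; n_term <- 0L

  for (a in anns) {
    gt_poly <- ensure_clockwise(annotation_polygon(a))
    b <- annotation_bbox(a)
    bw <- b[3] - b[1]; bh <- b[4] - b[2]
    if (bw < 6 || bh < 6) next
    # jittered oracle box, kept inside the image
    d <- stats::runif(4, -jitter, jitter)
    jb <- c(max(b[1] + d[1], 0), max(b[2] + d[2], 0),
            min(b[3] + d[3], W), min(b[4] + d[4], H))
    if (jb[3] - jb[1] < 4 || jb[4] - jb[2] < 4) jb <- as.numeric(b)
    box <- bbox(jb[1], jb[2], jb[3], jb[4])

    # --- extreme-point block ---
    dia <- resample_contour(box_to_diamond(box), cfg$n_diamond)
    vfe <- vertex_features(fg, dia)
    exf <- snake_block_forward(model$ex_block, vfe$vf)
    ai <- diamond_anchor_idx(cfg$n_diamond)
    gex <- contour_extremes(gt_poly)
    gt_pts <- rbind(gex$top, gex$rightmost, gex$bottom, gex$leftmost)
    pred_pts <- dia[ai, , drop = FALSE] + exf$out[ai, , drop = FALSE]
    sl <- smooth_l1(pred_pts, gt_pts)
    total <- total + mean(sl$value); n_term <- n_term + 1L
    dOff <- matrix(0, cfg$n_diamond, 2)
    dOff[ai, ] <- sl$grad / length(sl$value)
    exb <- snake_block_backward(model$ex_block, exf$cache, dOff)
    ex_g <- grads_add(ex_g, exb$grads)
    d_app <- exb$dvf[, seq_len(cfg$feature_dim), drop = FALSE]
    d_grids <- vf_backward_scatter(d_app, fg, vfe$plans, d_grids)

    # --- octagon from predicted extremes (detached), then deformation ---
    ex_pred <- list(top = pred_pts[1, ], rightmost = pred_pts[2, ],
                    bottom = pred_pts[3, ], leftmost = pred_pts[4, ])
    oct <- build_octagon(project_extremes(ex_pred, box), box)
    ct <- unclass(resample_contour(oct, cfg$n_contour))
    for (it in seq_len(cfg$iterations)) {
      vfd <- vertex_features(fg, ct)
      def <- snake_block_forward(model$de_block, vfd$vf)
      new_ct <- ct + def$out
      gt_n <- resample_contour(gt_poly, cfg$n_contour)
      tgt <- align_gt_to_pred(unclass(gt_n), ct)
      sl <- smooth_l1(new_ct, tgt)
      total <- total + mean(sl$value); n_term <- n_term + 1L
      deb <- snake_block_backward(model$de_block, def$cache,
                                  sl$grad / length(sl$value))
      de_g <- grads_add(de_g, deb$grads)
      d_app <- deb$dvf[, seq_len(cfg$feature_dim), drop = FALSE]
      d_grids <- vf_backward_scatter(d_app, fg, vfd$plans, d_grids)
      ct <- new_ct                       # detached between iterations
    }
  }
  if (is.null(ex_g)) return(NULL)
  feat_g <- conv_stack_backward(d_grids[[2]], model$feat, bb, arch,
                                extra = list(d_grids[[1]], NULL, NULL))
  list(loss = total / max(n_term, 1L),
       grads = list(feat = feat_g, ex_block = snake_block_grads_only(ex_g),
                    de_block = snake_block_grads_only(de_g)))
}

# Restrict block gradients to its numeric parameter fields (the block list
# also carries k/d_in/hidden metadata that SGD must not touch).
snake_block_grads_only <- function(g) g[c("cc1", "cc2", "fc1", "head")]

snake_params_of <- function(model) {
  list(feat = model$feat,
       ex_block = snake_block_grads_only(model$ex_block),
       de_block = snake_block_grads_only(model$de_block))
}

snake_params_into <- function(model, p) {
  model$feat <- p$feat
  model$ex_block[c("cc1", "cc2", "fc1", "head")] <- p$ex_block
  model$de_block[c("cc1", "cc2", "fc1", "head")] <- p$de_block
  model
}

#' Train the snake contour deformer
#'
#' SGD with momentum over the training-split images of a synthetic dataset,
#' in oracle-detector mode (ground-truth boxes, jittered). Records the
#' per-epoch mean loss in `model$loss_curve`.
#' @param dataset A `coco_dataset` with polygon annotations and in-memory
#'   images.
#' @param cfg A [snake_config()].
#' @param train_cfg List with `epochs`, `lr`, `momentum`, `weight_decay`,
#'   `grad_clip`, `batch_size` (defaults from [snake_train_config()]).
#' @param seed Integer seed (weights, shuffling, jitter).
#' @return A trained `snake_model`.
#' @export
train_snake <- function(dataset, cfg = snake_config(),
                        train_cfg = snake_train_config(), seed = 1L) {
  ids <- dataset_image_ids(dataset, split = "train")
  if (length(ids) == 0L) stop("data: empty dataset")
  model <- snake_init(cfg, seed = seed)
  params <- snake_params_of(model)
  state <- sgd_state_like(params)
  set.seed(seed + 1L)
  curve <- numeric(train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    # step decay: final third of the epochs at a tenth of the rate
    lr_ep <- train_cfg$lr *
      if (ep > ceiling(2 * train_cfg$epochs / 3)) 0.1 else 1
    ord <- sample(ids)
    ep_loss <- 0; nb <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + train_cfg$batch_size - 1L, length(ord))]
      i <- i + train_cfg$batch_size
      acc <- NULL; bl <- 0; nok <- 0L
      for (id in batch) {
        im <- dataset_image(dataset, id)
        anns <- dataset_annotations_for(dataset, id)
        model <- snake_params_into(model, params)
        st <- snake_image_step(model, im$array, anns,
                               jitter = train_cfg$jitter)
        if (is.null(st)) next
        acc <- grads_add(acc, st$grads)
        bl <- bl + st$loss; nok <- nok + 1L
      }
      if (is.null(acc)) next
      acc <- grads_clip(grads_scale(acc, 1 / nok), train_cfg$grad_clip)
      up <- sgd_step(params, acc, state, lr = lr_ep,
                     momentum = train_cfg$momentum,
                     weight_decay = train_cfg$weight_decay)
      params <- up$p; state <- up$v
      ep_loss <- ep_loss + bl / nok; nb <- nb + 1
    }
    curve[ep] <- ep_loss / max(nb, 1)
  }
  model <- snake_params_into(model, params)
  model$loss_curve <- curve
  model
}

#' Default snake training configuration
#' @param epochs Passes over the training split.
#' @param lr,momentum,weight_decay SGD settings.
#' @param batch_size Images per SGD step.
#' @param jitter Oracle-box jitter amplitude, pixels.
#' @param grad_clip Global gradient-norm clip.
#' @export
snake_train_config <- function(epochs = 10L, lr = 0.01, momentum = 0.9,
                               weight_decay = 1e-4, batch_size = 2L,
                               jitter = 1.5, grad_clip = 5) {
  list(epochs = as.integer(epochs), lr = lr, momentum = momentum,
       weight_decay = weight_decay, batch_size = as.integer(batch_size),
       jitter = jitter, grad_clip = grad_clip)
}

#' Evaluate the snake on held-out annotations (oracle boxes)
#'
#' Runs the full contour approximation per annotation with the ground-truth
#' box as input and scores each iteration's contour against the
#' ground-truth polygon by mask IoU at image resolution.
#' @param model A trained `snake_model`.
#' @param dataset A `coco_dataset`.
#' @param split Which split to evaluate (default "val").
#' @param max_images Optional cap on evaluated images.
#' @return A data frame with one row per (instance, iteration): `image_id`,
#'   `ann_id`, `iteration`, `iou`, plus iteration 0 (the initial octagon).
#' @export
evaluate_snake <- function(model, dataset, split = "val",
                           max_images = Inf) {
  ids <- dataset_image_ids(dataset, split = split)
  if (length(ids) > max_images) ids <- ids[seq_len(max_images)]
  rows <- list()
  for (id in ids) {
    im <- dataset_image(dataset, id)
    fg <- snake_features(model, im$array)
    for (a in dataset_annotations_for(dataset, id)) {
      b <- annotation_bbox(a)
      if (b[3] - b[1] < 6 || b[4] - b[2] < 6) next
      gt_poly <- annotation_polygon(a)
      gt_mask <- contour_to_mask(gt_poly, im$height, im$width)
      res <- snake_segment(model, b, fg, trace = TRUE)
      stages <- c(list(res$octagon), res$iterations)
      for (k in seq_along(stages)) {
        m <- contour_to_mask(stages[[k]], im$height, im$width)
        rows[[length(rows) + 1L]] <- data.frame(
          image_id = id, ann_id = a$id, iteration = k - 1L,
          iou = mask_iou(gt_mask, m))
      }
    }
  }
  do.call(rbind, rows)
}
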