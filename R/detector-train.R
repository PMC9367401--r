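#' @title Two-stage few-shot training
#' @description Base training on abundant base-class images (all parameters
#'   updated), then fine-tuning on a balanced n-shot subset covering base and
#'   novel classes with the feature extractor frozen: novel-class rows of the
#'   box classifier are randomly initialized and only the box predictor
#'   (classifier + regressor) is updated.
#' @name fewshot
NULL

#' Training configuration
#'
#' Defaults follow the standard few-shot detection recipe at desk scale:
#' SGD with batch size 2, momentum 0.9, weight decay 0.0001, learning rate
#' 0.02 for base training and 0.001 for fine-tuning.
#' @param batch_size Images per SGD step.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param lr_base Learning rate for base training.
#' @param lr_finetune Learning rate for fine-tuning.
#' @param n_shot Images per class in the fine-tuning subset.
#' @param seed Integer seed.
#' @param epochs_base,epochs_finetune Training epochs for each stage.
#' @param grad_clip Global gradient-norm clip (numerical guard).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 2L, momentum = 0.9,
                         weight_decay = 1e-4, lr_base = 0.02,
                         lr_finetune = 0.001, n_shot = 5L, seed = 1L,
                         epochs_base = 6L, epochs_finetune = 40L,
                         grad_clip = 5) {
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, lr_base = lr_base,
                 lr_finetune = lr_finetune, n_shot = as.integer(n_shot),
                 seed = as.integer(seed),
                 epochs_base = as.integer(epochs_base),
                 epochs_finetune = as.integer(epochs_finetune),
                 grad_clip = grad_clip),
            class = "train_config")
}

#' Split categories into base and novel classes
#'
#' @param categories Vector of category ids (or a `coco_dataset` categories
#'   list).
#' @param ratio Base:novel ratio (default 3, i.e. 3:1 — 9 base and 3 novel
#'   classes for 12 categories).
#' @param seed Integer seed; the split is a deterministic function of it.
#' @return List with sorted `base_classes` and `novel_classes`.
#' @export
split_base_novel <- function(categories, ratio = 3, seed = 1L) {
  if (is.list(categories)) {
    categories <- vapply(categories, `[[`, integer(1), "id")
  }
  categories <- as.integer(categories)
  n <- length(categories)
  if (n < 2L) stop("parameter: need at least 2 categories")
  n_novel <- max(1L, as.integer(floor(n / (ratio + 1))))
  set.seed(as.integer(seed))
  novel <- sort(sample(categories, n_novel))
  list(base_classes = sort(setdiff(categories, novel)),
       novel_classes = novel)
}

#' Build a balanced n-shot fine-tuning subset
#'
#' Picks exactly `n` training-split images per class over base and novel
#' classes (n-shot: n images of each class).
#' @param dataset A `coco_dataset`.
#' @param split A [split_base_novel()] result.
#' @param n Images per class.
#' @param seed Integer seed.
#' @return A `coco_dataset` restricted to the sampled images.
#' @export
build_nshot_subset <- function(dataset, split, n, seed = 1L) {
  n <- as.integer(n)
  all_cls <- c(split$base_classes, split$novel_classes)
  set.seed(as.integer(seed))
  keep_ids <- integer(0)
  for (cl in all_cls) {
    ids <- dataset_image_ids(dataset, split = "train", class_id = cl)
    if (length(ids) < n) {
      stop(sprintf("data: class %d has only %d training images (< %d-shot)",
                   cl, length(ids), n))
    }
    keep_ids <- c(keep_ids, sample(ids, n))
  }
  subset_dataset(dataset, keep_ids)
}

subset_dataset <- function(dataset, image_ids) {
  imgs <- Filter(function(im) im$id %in% image_ids, dataset$images)
  anns <- Filter(function(a) a$image_id %in% image_ids, dataset$annotations)
  structure(list(images = imgs, annotations = anns,
                 categories = dataset$categories, classes = dataset$classes,
                 manifest = NULL, image_size = dataset$image_size),
            class = "coco_dataset")
}

# ---- loss + backward for one image ---------------------------------------

# Random jittered copies of ground-truth boxes (augmentation so the ROI head
# sees imperfect localizations).
jitter_boxes <- function(gt, n_copies = 2L, frac = 0.1) {
  out <- NULL
  for (i in seq_len(nrow(gt))) {
    w <- gt[i, 3] - gt[i, 1]; h <- gt[i, 4] - gt[i, 2]
    for (j in seq_len(n_copies)) {
      d <- stats::runif(4, -frac, frac) * c(w, h, w, h)
      out <- rbind(out, gt[i, ] + d)
    }
  }
  out
}

# Forward + loss + full backward for one training image. Returns gradients
# for extractor and predictor plus the scalar total loss.
detector_image_step <- function(model, img, gt_boxes, gt_classes,
                                update_extractor = TRUE) {
  cfg <- model$cfg
  fw <- detector_backbone_forward(model, img)
  A <- cfg$n_anchors
  K <- length(model$class_ids)
  anchors <- make_anchors(fw$Hf, fw$Wf, fw$stride, cfg)
  fl <- rpn_flat(fw, cfg)
  nA <- nrow(anchors)

  # --- RPN targets ---
  iou <- box_iou_matrix(anchors, gt_boxes)        # nA x nG
  best_gt <- max.col(iou, ties.method = "first")
  best_iou <- iou[cbind(seq_len(nA), best_gt)]
  pos <- best_iou >= 0.5
  for (g in seq_len(ncol(iou))) pos[which.max(iou[, g])] <- TRUE
  neg <- best_iou < 0.3 & !pos
  pos_idx <- which(pos); neg_idx <- which(neg)
  if (length(pos_idx) > 8L) pos_idx <- sample(pos_idx, 8L)
  n_neg <- min(length(neg_idx), 32L - length(pos_idx))
  if (length(neg_idx) > n_neg) neg_idx <- sample(neg_idx, n_neg)
  samp <- c(pos_idx, neg_idx)
  tgt <- c(rep(1, length(pos_idx)), rep(0, length(neg_idx)))

  bce <- bce_logits(fl$obj[samp], tgt)
  d_obj_flat <- numeric(nA)
  d_obj_flat[samp] <- bce$grad

  d_reg_flat <- matrix(0, nA, 4)
  rpn_reg_loss <- 0
  if (length(pos_idx) > 0L) {
    t_enc <- encode_boxes(anchors[pos_idx, , drop = FALSE],
                          gt_boxes[best_gt[pos_idx], , drop = FALSE])
    sl <- smooth_l1(fl$reg[pos_idx, , drop = FALSE], t_enc)
    rpn_reg_loss <- mean(sl$value)
    d_reg_flat[pos_idx, ] <- sl$grad / length(sl$value)
  }

  # un-flatten anchor-major gradients back to [P, A] / [P, 4A] layout
  d_obj_mat <- t(matrix(d_obj_flat, A, nA %/% A))
  d_reg_mat <- matrix(0, nA %/% A, 4L * A)
  for (j in 1:4) {
    d_reg_mat[, (j - 1) * A + seq_len(A)] <- t(matrix(d_reg_flat[, j], A))
  }

  # --- ROI head ---
  pr <- gen_proposals(fw, cfg, pre_nms = 128L, post_nms = 16L)
  rois <- rbind(pr$boxes, gt_boxes, jitter_boxes(gt_boxes))
  rois <- clip_boxes(rois, fw$W, fw$H)
  ok <- (rois[, 3] - rois[, 1] > 2) & (rois[, 4] - rois[, 2] > 2)
  rois <- rois[ok, , drop = FALSE]
  riou <- box_iou_matrix(rois, gt_boxes)
  r_best <- max.col(riou, ties.method = "first")
  r_iou <- riou[cbind(seq_len(nrow(rois)), r_best)]
  fg <- which(r_iou >= 0.5)
  bg <- which(r_iou < 0.4)
  if (length(fg) > 8L) fg <- sample(fg, 8L)
  nbg <- min(length(bg), 16L - length(fg))
  if (length(bg) > nbg) bg <- sample(bg, nbg)
  sel <- c(fg, bg)
  rois_s <- rois[sel, , drop = FALSE]
  labels <- rep(K + 1L, length(sel))                       # background
  if (length(fg) > 0L) {
    labels[seq_along(fg)] <- match(gt_classes[r_best[fg]], model$class_ids)
  }

  rf <- roi_features_forward(model, fw, rois_s)
  hd <- predictor_forward(model, rf$fc)
  ce <- cross_entropy(hd$cls, labels)
  cls_bw <- dense_backward(ce$grad, rf$fc, model$predictor$cls)

  reg_loss <- 0
  d_fc_reg <- 0
  reg_grad <- list(W = model$predictor$reg$W * 0,
                   b = model$predictor$reg$b * 0)
  if (length(fg) > 0L) {
    t_enc <- encode_boxes(rois_s[seq_along(fg), , drop = FALSE],
                          gt_boxes[r_best[fg], , drop = FALSE])
    sl <- smooth_l1(hd$reg[seq_along(fg), , drop = FALSE], t_enc)
    reg_loss <- mean(sl$value)
    d_reg_out <- matrix(0, length(sel), 4)
    d_reg_out[seq_along(fg), ] <- sl$grad / length(sl$value)
    reg_bw <- dense_backward(d_reg_out, rf$fc, model$predictor$reg)
    reg_grad <- reg_bw$grad
    d_fc_reg <- reg_bw$dX
  }

  pred_grads <- list(cls = cls_bw$grad, reg = reg_grad)
  total <- bce$value + rpn_reg_loss + ce$value + reg_loss

  if (!update_extractor) {
    return(list(loss = total, pred_grads = pred_grads, ext_grads = NULL))
  }

  # --- backward into the extractor ---
  d_fc <- cls_bw$dX + d_fc_reg
  d_fc_pre <- relu_backward(d_fc, rf$fc)
  fc_bw <- dense_backward(d_fc_pre, rf$F, model$extractor$fc)
  dF <- fc_bw$dX                                           # n x (bins^2*C)
  n <- rf$n; b2 <- rf$bins^2; C <- rf$C
  dS <- aperm(array(dF, c(n, b2, C)), c(2, 1, 3))
  dim(dS) <- c(n * b2, C)
  d_grid_roi <- bilinear_backward(dS, fw$bb$out, rf$plan)

  obj_bw <- dense_backward(d_obj_mat, fw$rpn_act, model$extractor$rpn_obj)
  regh_bw <- dense_backward(d_reg_mat, fw$rpn_act, model$extractor$rpn_reg)
  d_ra <- relu_backward(obj_bw$dX + regh_bw$dX, fw$rpn_act)
  rpn_bw <- conv_backward(d_ra, model$extractor$rpn_conv, fw$rpn_plan,
                          fw$rpn_patches, need_dx = TRUE)

  d_grid <- d_grid_roi + rpn_bw$dX
  bb_grads <- conv_stack_backward(d_grid, model$extractor$backbone,
                                  fw$bb, model$arch)

  list(loss = total,
       pred_grads = pred_grads,
       ext_grads = list(backbone = bb_grads, rpn_conv = rpn_bw$grad,
                        rpn_obj = obj_bw$grad, rpn_reg = regh_bw$grad,
                        fc = fc_bw$grad))
}

grads_scale <- function(g, s) rapply(g, function(x) x * s, how = "replace")

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) grads_add(a[[nm]], b[[nm]])
    else a[[nm]] + b[[nm]]
  }
  a
}

grads_norm <- function(g) {
  sqrt(sum(unlist(rapply(g, function(x) sum(x^2), how = "unlist"))))
}

grads_clip <- function(g, clip) {
  nrm <- grads_norm(g)
  if (is.finite(nrm) && nrm > clip) g <- grads_scale(g, clip / nrm)
  g
}

gt_of_image <- function(dataset, image_id) {
  anns <- dataset_annotations_for(dataset, image_id)
  if (length(anns) == 0L) return(NULL)
  boxes <- do.call(rbind, lapply(anns, function(a)
    as.numeric(annotation_bbox(a))))
  classes <- vapply(anns, function(a) as.integer(a$category_id), integer(1))
  list(boxes = boxes, classes = classes)
}

#' Base-train the detector on abundant base-class images
#'
#' SGD over the training-split images of the base classes; every parameter
#' group (backbone, RPN, FC, box predictor) is updated. The per-epoch mean
#' total loss (RPN objectness + RPN regression + classification + box
#' regression) is recorded in `model$loss_curve`.
#' @param model An `fsod_model` covering exactly the base classes.
#' @param base_dataset A `coco_dataset` whose annotations contain only base
#'   classes (novel-class annotations are an error).
#' @param cfg A [train_config()].
#' @return The trained model.
#' @export
base_train <- function(model, base_dataset, cfg = train_config()) {
  cats <- unique(vapply(base_dataset$annotations, function(a)
    as.integer(a$category_id), integer(1)))
  if (!all(cats %in% model$class_ids)) {
    stop("data: base dataset contains novel-class annotations")
  }
  ids <- dataset_image_ids(base_dataset, split = "train")
  if (length(ids) == 0L) stop("data: empty base dataset")
  params <- list(extractor = model$extractor, predictor = model$predictor)
  state <- sgd_state_like(params)
  set.seed(cfg$seed)
  curve <- numeric(cfg$epochs_base)
  for (ep in seq_len(cfg$epochs_base)) {
    ord <- sample(ids)
    ep_loss <- 0; nb <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      i <- i + cfg$batch_size
      acc <- NULL; bl <- 0
      for (id in batch) {
        gt <- gt_of_image(base_dataset, id)
        if (is.null(gt)) next
        img <- dataset_image(base_dataset, id)$array
        model$extractor <- params$extractor
        model$predictor <- params$predictor
        st <- detector_image_step(model, img, gt$boxes, gt$classes)
        acc <- grads_add(acc, list(extractor = st$ext_grads,
                                   predictor = st$pred_grads))
        bl <- bl + st$loss
      }
      if (is.null(acc)) next
      acc <- grads_clip(grads_scale(acc, 1 / length(batch)), cfg$grad_clip)
      up <- sgd_step(params, acc, state, lr = cfg$lr_base,
                     momentum = cfg$momentum,
                     weight_decay = cfg$weight_decay)
      params <- up$p; state <- up$v
      ep_loss <- ep_loss + bl / length(batch); nb <- nb + 1
    }
    curve[ep] <- ep_loss / max(nb, 1)
  }
  model$extractor <- params$extractor
  model$predictor <- params$predictor
  model$trained_base <- TRUE
  model$loss_curve <- curve
  model
}

#' Fine-tune the box predictor on a balanced n-shot subset
#'
#' The feature extractor (backbone, RPN, FC) is bitwise frozen. The box
#' classifier is extended with randomly initialized rows (zero-mean
#' Gaussian, sd 0.01) for the novel classes, and only the box predictor
#' (classifier + regressor) is updated, at the fine-tuning learning rate.
#' Frozen-extractor ROI features are cached once per subset image, which
#' makes fine-tuning cheap.
#' @param model A base-trained `fsod_model`.
#' @param subset A balanced subset from [build_nshot_subset()].
#' @param split The [split_base_novel()] result.
#' @param cfg A [train_config()].
#' @return The fine-tuned model covering base + novel classes.
#' @export
fine_tune <- function(model, subset, split, cfg = train_config()) {
  if (!isTRUE(model$trained_base)) {
    stop("state: model must be base-trained before fine-tuning")
  }
  novel <- setdiff(split$novel_classes, model$class_ids)
  set.seed(cfg$seed)
  K_old <- length(model$class_ids)
  fdim <- nrow(model$predictor$cls$W)
  Wc <- model$predictor$cls$W; bc <- model$predictor$cls$b
  W_new <- cbind(Wc[, seq_len(K_old), drop = FALSE],
                 matrix(stats::rnorm(fdim * length(novel), sd = 0.01),
                        fdim, length(novel)),
                 Wc[, K_old + 1L])
  b_new <- c(bc[seq_len(K_old)], numeric(length(novel)), bc[K_old + 1L])
  model$predictor$cls <- list(W = W_new, b = b_new)
  model$class_ids <- c(model$class_ids, as.integer(novel))
  K <- length(model$class_ids)

  # frozen-extractor caches: sampled ROIs, labels, regression targets
  ids <- dataset_image_ids(subset, split = "train")
  caches <- list()
  for (id in ids) {
    gt <- gt_of_image(subset, id)
    if (is.null(gt)) next
    img <- dataset_image(subset, id)$array
    fw <- detector_backbone_forward(model, img)
    pr <- gen_proposals(fw, model$cfg, pre_nms = 128L, post_nms = 16L)
    rois <- clip_boxes(rbind(pr$boxes, gt$boxes, jitter_boxes(gt$boxes)),
                       fw$W, fw$H)
    ok <- (rois[, 3] - rois[, 1] > 2) & (rois[, 4] - rois[, 2] > 2)
    rois <- rois[ok, , drop = FALSE]
    riou <- box_iou_matrix(rois, gt$boxes)
    r_best <- max.col(riou, ties.method = "first")
    r_iou <- riou[cbind(seq_len(nrow(rois)), r_best)]
    keep <- which(r_iou >= 0.5 | r_iou < 0.4)
    rois <- rois[keep, , drop = FALSE]
    r_best <- r_best[keep]; r_iou <- r_iou[keep]
    labels <- ifelse(r_iou >= 0.5,
                     match(gt$classes[r_best], model$class_ids), K + 1L)
    rf <- roi_features_forward(model, fw, rois)
    tgt <- encode_boxes(rois, gt$boxes[r_best, , drop = FALSE])
    caches[[length(caches) + 1L]] <-
      list(fc = rf$fc, labels = labels, tgt = tgt, pos = r_iou >= 0.5)
  }
  if (length(caches) == 0L) stop("data: empty fine-tuning subset")

  params <- model$predictor
  state <- sgd_state_like(params)
  curve <- numeric(cfg$epochs_finetune)
  for (ep in seq_len(cfg$epochs_finetune)) {
    ord <- sample(seq_along(caches))
    ep_loss <- 0; nb <- 0
    i <- 1L
    while (i <= length(ord)) {
      batch <- ord[i:min(i + cfg$batch_size - 1L, length(ord))]
      i <- i + cfg$batch_size
      acc <- NULL; bl <- 0
      for (ci in batch) {
        ch <- caches[[ci]]
        hd <- list(cls = dense_forward(ch$fc, params$cls),
                   reg = dense_forward(ch$fc, params$reg))
        ce <- cross_entropy(hd$cls, ch$labels)
        cls_bw <- dense_backward(ce$grad, ch$fc, params$cls, need_dx = FALSE)
        reg_grad <- list(W = params$reg$W * 0, b = params$reg$b * 0)
        reg_loss <- 0
        if (any(ch$pos)) {
          sl <- smooth_l1(hd$reg[ch$pos, , drop = FALSE],
                          ch$tgt[ch$pos, , drop = FALSE])
          reg_loss <- mean(sl$value)
          d_reg <- matrix(0, nrow(ch$fc), 4)
          d_reg[ch$pos, ] <- sl$grad / length(sl$value)
          reg_bw <- dense_backward(d_reg, ch$fc, params$reg, need_dx = FALSE)
          reg_grad <- reg_bw$grad
        }
        acc <- grads_add(acc, list(cls = cls_bw$grad, reg = reg_grad))
        bl <- bl + ce$value + reg_loss
      }
      if (is.null(acc)) next
      acc <- grads_clip(grads_scale(acc, 1 / length(batch)), cfg$grad_clip)
      up <- sgd_step(params, acc, state, lr = cfg$lr_finetune,
                     momentum = cfg$momentum,
                     weight_decay = cfg$weight_decay)
      params <- up$p; state <- up$v
      ep_loss <- ep_loss + bl / length(batch); nb <- nb + 1
    }
    curve[ep] <- ep_loss / max(nb, 1)
  }
  model$predictor <- params
  model$finetune_curve <- curve
  model$fine_tuned <- TRUE
  model
}
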