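#' @title Few-shot object detector
#' @description Scaled-down two-stage detector with the canonical structure:
#'   a strided convolutional backbone, a single-scale region proposal
#'   network (9 anchors per location), ROI pooling, a fully connected layer,
#'   and a box predictor made of a box classifier and a box regressor. The
#'   backbone + RPN + FC layers form the feature extractor (frozen at
#'   fine-tuning time); only the classifier/regressor heads are tuned on
#'   n-shot subsets.
#' @name detector
NULL

detector_arch <- function() {
  list(c(3, 2, 3, 12), c(3, 2, 12, 24), c(3, 1, 24, 24),
       c(3, 1, 24, 24), c(3, 1, 24, 24), c(3, 1, 24, 24))
}

#' Detector hyperparameter configuration
#'
#' Anchor layout and head sizes for the desk-scale detector. 9 anchors per
#' feature-map location: 3 scales x 3 aspect ratios at a single feature
#' level (stride 4).
#' @param anchor_scales Anchor box side lengths, pixels.
#' @param anchor_ratios Height/width aspect ratios.
#' @param roi_bins ROI pooling grid side (bins x bins sample points).
#' @param fc_dim Width of the FC layer after ROI pooling.
#' @return A `detector_config` list.
#' @export
detector_config <- function(anchor_scales = c(16, 32, 64),
                            anchor_ratios = c(0.5, 1, 2),
                            roi_bins = 3L, fc_dim = 96L) {
  structure(list(anchor_scales = anchor_scales,
                 anchor_ratios = anchor_ratios,
                 roi_bins = as.integer(roi_bins),
                 fc_dim = as.integer(fc_dim),
                 n_anchors = length(anchor_scales) * length(anchor_ratios)),
            class = "detector_config")
}

#' Initialize a few-shot detector model
#'
#' @param class_ids Category ids the box predictor covers initially (the
#'   base classes for base training).
#' @param cfg A [detector_config()].
#' @param seed Integer seed for weight initialization.
#' @return An `fsod_model` list with `extractor` (backbone, rpn, fc) and
#'   `predictor` (cls, reg) parameter groups.
#' @export
fsod_init <- function(class_ids, cfg = detector_config(), seed = 1L) {
  set.seed(seed)
  arch <- detector_arch()
  cbb <- arch[[length(arch)]][4]
  na <- cfg$n_anchors
  fdim <- cfg$roi_bins^2 * cbb
  structure(list(
    cfg = cfg,
    arch = arch,
    class_ids = as.integer(class_ids),
    extractor = list(
      backbone = conv_stack_init(arch),
      rpn_conv = nn_init_conv(3L, cbb, cbb),
      rpn_obj = nn_init_dense(cbb, na, scale = 0.01),
      rpn_reg = nn_init_dense(cbb, 4L * na, scale = 0.01),
      fc = nn_init_dense(fdim, cfg$fc_dim)
    ),
    predictor = list(
      cls = nn_init_dense(cfg$fc_dim, length(class_ids) + 1L, scale = 0.01),
      reg = nn_init_dense(cfg$fc_dim, 4L, scale = 0.01)
    ),
    trained_base = FALSE
  ), class = "fsod_model")
}

#' @export
print.fsod_model <- function(x, ...) {
  cat(sprintf("<fsod_model: %d classes (+background), base-trained: %s>\n",
              length(x$class_ids), x$trained_base))
  invisible(x)
}

# ---- anchors and box coding ----------------------------------------------

# All anchors for a Hf x Wf feature grid at `stride`, as an (P*A) x 4 matrix
# of corner boxes, anchor-major within each position.
make_anchors <- function(Hf, Wf, stride, cfg) {
  cy <- rep((seq_len(Hf) - 0.5) * stride, times = Wf)
  cx <- rep((seq_len(Wf) - 0.5) * stride, each = Hf)
  shapes <- do.call(rbind, lapply(cfg$anchor_scales, function(s) {
    t(vapply(cfg$anchor_ratios, function(r) {
      c(w = s / sqrt(r), h = s * sqrt(r))
    }, numeric(2)))
  }))
  A <- nrow(shapes)
  P <- Hf * Wf
  cxa <- rep(cx, each = A); cya <- rep(cy, each = A)
  w <- rep(shapes[, 1], times = P); h <- rep(shapes[, 2], times = P)
  cbind(cxa - w / 2, cya - h / 2, cxa + w / 2, cya + h / 2)
}

# Standard box-delta encoding relative to reference boxes (corner form).
encode_boxes <- function(ref, gt) {
  rw <- ref[, 3] - ref[, 1]; rh <- ref[, 4] - ref[, 2]
  rx <- ref[, 1] + rw / 2;   ry <- ref[, 2] + rh / 2
  gw <- gt[, 3] - gt[, 1];   gh <- gt[, 4] - gt[, 2]
  gx <- gt[, 1] + gw / 2;    gy <- gt[, 2] + gh / 2
  cbind((gx - rx) / rw, (gy - ry) / rh, log(gw / rw), log(gh / rh))
}

decode_boxes <- function(ref, deltas) {
  rw <- ref[, 3] - ref[, 1]; rh <- ref[, 4] - ref[, 2]
  rx <- ref[, 1] + rw / 2;   ry <- ref[, 2] + rh / 2
  d <- pmin(pmax(deltas, -4), 4)  # guard exp overflow
  cx <- rx + d[, 1] * rw; cy <- ry + d[, 2] * rh
  w <- rw * exp(d[, 3]);  h <- rh * exp(d[, 4])
  cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
}

clip_boxes <- function(B, width, height) {
  B[, 1] <- pmin(pmax(B[, 1], 0), width)
  B[, 3] <- pmin(pmax(B[, 3], 0), width)
  B[, 2] <- pmin(pmax(B[, 2], 0), height)
  B[, 4] <- pmin(pmax(B[, 4], 0), height)
  B
}

#' Greedy non-maximum suppression
#'
#' Boxes are processed in descending score order (ties broken by original
#' index); a box is kept if its IoU with every already-kept box is at most
#' `iou_threshold`.
#' @param boxes n x 4 matrix of corner-form boxes.
#' @param scores Length-n scores.
#' @param iou_threshold Suppression threshold.
#' @return Indices of kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_threshold = 0.5) {
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(-scores, seq_len(n))
  keep <- integer(0)
  while (length(ord) > 0L) {
    i <- ord[1]
    keep <- c(keep, i)
    if (length(ord) == 1L) break
    rest <- ord[-1]
    iou <- box_iou_matrix(boxes[i, , drop = FALSE],
                          boxes[rest, , drop = FALSE])[1, ]
    ord <- rest[iou <= iou_threshold]
  }
  keep
}

# ---- forward passes ------------------------------------------------------

# Backbone + RPN forward for one image. Returns the feature grid, the RPN
# activations/outputs and the caches needed for backprop.
detector_backbone_forward <- function(model, img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  bb <- conv_stack_forward(model$extractor$backbone, image_to_matrix(img),
                           model$arch, H, W)
  stride <- conv_stack_stride(model$arch)
  rpn_plan <- conv_plan(bb$out_h, bb$out_w, 3L, 1L)
  rc <- conv_forward(bb$out, model$extractor$rpn_conv, rpn_plan)
  ra <- relu(rc$out)
  obj <- dense_forward(ra, model$extractor$rpn_obj)      # P x A
  reg <- dense_forward(ra, model$extractor$rpn_reg)      # P x 4A
  list(bb = bb, stride = stride, H = H, W = W,
       Hf = bb$out_h, Wf = bb$out_w,
       rpn_plan = rpn_plan, rpn_patches = rc$patches, rpn_act = ra,
       obj = obj, reg = reg)
}

# Flatten RPN outputs to per-anchor vectors (anchor-major within position,
# position order = raster column-major, matching make_anchors).
rpn_flat <- function(fw, cfg) {
  A <- cfg$n_anchors
  obj <- as.vector(t(fw$obj))                 # (P*A), anchor fast
  reg <- matrix(0, nrow(fw$reg) * A, 4)
  for (j in 1:4) reg[, j] <- as.vector(t(fw$reg[, (j - 1) * A + seq_len(A)]))
  list(obj = obj, reg = reg)
}

# Proposal generation from RPN outputs.
gen_proposals <- function(fw, cfg, pre_nms = 200L, post_nms = 30L,
                          nms_iou = 0.7, min_size = 2) {
  anchors <- make_anchors(fw$Hf, fw$Wf, fw$stride, cfg)
  fl <- rpn_flat(fw, cfg)
  scores <- sigmoid(fl$obj)
  take <- utils::head(order(-scores, seq_along(scores)), pre_nms)
  boxes <- decode_boxes(anchors[take, , drop = FALSE],
                        fl$reg[take, , drop = FALSE])
  boxes <- clip_boxes(boxes, fw$W, fw$H)
  ok <- (boxes[, 3] - boxes[, 1] >= min_size) &
    (boxes[, 4] - boxes[, 2] >= min_size)
  boxes <- boxes[ok, , drop = FALSE]
  sc <- scores[take][ok]
  if (nrow(boxes) == 0L) return(list(boxes = boxes, scores = sc))
  keep <- utils::head(nms(boxes, sc, nms_iou), post_nms)
  list(boxes = boxes[keep, , drop = FALSE], scores = sc[keep])
}

# ROI feature extraction: roi_bins^2 sample points per box, bilinearly
# sampled from the backbone feature grid, flattened per ROI.
roi_sample_coords <- function(boxes, bins) {
  n <- nrow(boxes)
  g <- (seq_len(bins) - 0.5) / bins
  bx <- rep(g, times = bins)    # bin-major: x fast
  by <- rep(g, each = bins)
  w <- boxes[, 3] - boxes[, 1]; h <- boxes[, 4] - boxes[, 2]
  # rows: roi-major (roi 1 bins 1..B^2, roi 2, ...)
  x <- rep(boxes[, 1], each = bins^2) + rep(w, each = bins^2) * rep(bx, n)
  y <- rep(boxes[, 2], each = bins^2) + rep(h, each = bins^2) * rep(by, n)
  cbind(x, y)
}

roi_features_forward <- function(model, fw, boxes) {
  bins <- model$cfg$roi_bins
  n <- nrow(boxes)
  coords <- roi_sample_coords(boxes, bins)
  pl <- bilinear_plan(coords[, 1], coords[, 2], fw$Hf, fw$Wf, fw$stride)
  S <- bilinear_sample(fw$bb$out, pl)          # (n*bins^2) x C
  C <- ncol(S)
  F <- aperm(array(S, c(bins^2, n, C)), c(2, 1, 3))
  dim(F) <- c(n, bins^2 * C)
  fc_pre <- dense_forward(F, model$extractor$fc)
  fc <- relu(fc_pre)
  list(F = F, fc = fc, plan = pl, n = n, bins = bins, C = C)
}

predictor_forward <- function(model, fc) {
  list(cls = dense_forward(fc, model$predictor$cls),
       reg = dense_forward(fc, model$predictor$reg))
}

# Frozen-extractor cache for one image: everything up to FC features for
# eval-mode proposals. Reusable across any predictor heads.
detector_image_cache <- function(model, img, pre_nms = 200L, post_nms = 30L) {
  fw <- detector_backbone_forward(model, img)
  pr <- gen_proposals(fw, model$cfg, pre_nms = pre_nms, post_nms = post_nms)
  rf <- if (nrow(pr$boxes) > 0L) roi_features_forward(model, fw, pr$boxes)
  list(proposals = pr$boxes, prop_scores = pr$scores,
       fc = if (is.null(rf)) NULL else rf$fc, H = fw$H, W = fw$W)
}

# Apply predictor heads to a cached image; returns detection list.
detect_from_cache <- function(model, cache, score_threshold = 0.05,
                              nms_iou = 0.5, max_det = 100L) {
  if (is.null(cache$fc) || nrow(cache$proposals) == 0L) return(list())
  hd <- predictor_forward(model, cache$fc)
  P <- softmax_rows(hd$cls)
  boxes <- decode_boxes(cache$proposals, hd$reg)
  boxes <- clip_boxes(boxes, cache$W, cache$H)
  K <- length(model$class_ids)
  dets <- list()
  for (k in seq_len(K)) {
    sc <- P[, k]
    sel <- which(sc >= score_threshold &
                   boxes[, 3] > boxes[, 1] & boxes[, 4] > boxes[, 2])
    if (length(sel) == 0L) next
    keep <- nms(boxes[sel, , drop = FALSE], sc[sel], nms_iou)
    for (i in keep) {
      b <- boxes[sel[i], ]
      dets[[length(dets) + 1L]] <- list(
        box = bbox(b[1], b[2], b[3], b[4]),
        category_id = model$class_ids[k],
        score = sc[sel[i]]
      )
    }
  }
  if (length(dets) == 0L) return(dets)
  ord <- order(-vapply(dets, `[[`, numeric(1), "score"),
               seq_along(dets))
  utils::head(dets[ord], max_det)
}

#' Detect objects in an image
#'
#' Full detector forward pass: backbone features, RPN proposals, ROI
#' pooling + FC, box classifier and regressor, then per-class greedy NMS.
#' Detections are returned sorted by descending score (ties broken by
#' construction order).
#' @param model A trained `fsod_model`.
#' @param img `[H, W, 3]` numeric array in `[0, 1]`.
#' @param score_threshold Minimum class score (default 0.05, the standard
#'   evaluation convention).
#' @param nms_iou Per-class NMS threshold (default 0.5).
#' @param max_det Maximum detections per image.
#' @return List of detections: `box` ([bbox()]), `category_id`, `score`.
#' @export
detect <- function(model, img, score_threshold = 0.05, nms_iou = 0.5,
                   max_det = 100L) {
  if (dim(img)[1] < conv_stack_stride(model$arch) ||
      dim(img)[2] < conv_stack_stride(model$arch)) {
    stop("data: image smaller than the backbone stride")
  }
  cache <- detector_image_cache(model, img)
  detect_from_cache(model, cache, score_threshold, nms_iou, max_det)
}
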