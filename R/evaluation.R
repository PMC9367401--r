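#' @title COCO-style detection and segmentation evaluation
#' @description Greedy score-ordered matching of detections to ground truth
#'   at an IoU threshold, 101-point interpolated average precision, and the
#'   AP / AP50 / AP75 summary (AP averaged over IoU thresholds
#'   0.50:0.05:0.95 and over categories, reported on the 0-100 scale).
#'   Box mode matches by box IoU, mask mode by rasterized polygon IoU.
#' @name evaluation
NULL

det_scores <- function(dets) vapply(dets, `[[`, numeric(1), "score")

#' Match detections of one image to ground truth at an IoU threshold
#'
#' Detections must be sorted by descending score; each detection greedily
#' claims the unclaimed ground truth with the highest IoU, provided that
#' IoU reaches the threshold. Each ground truth is matched at most once.
#' @param dets List of detections (`box`, `score`, and in mask mode
#'   `contour`), sorted by descending score.
#' @param gts List of ground truths (`box`, and in mask mode `polygon`).
#' @param iou_threshold Matching threshold.
#' @param mode `"box"` or `"mask"`.
#' @param height,width Raster size for mask mode.
#' @return List: `tp` logical per detection, `matched_gt` index (NA if
#'   none), `unmatched_gt` count.
#' @export
match_detections <- function(dets, gts, iou_threshold, mode = "box",
                             height = NULL, width = NULL) {
  nd <- length(dets); ng <- length(gts)
  if (nd > 1L) {
    sc <- det_scores(dets)
    if (any(diff(sc) > 1e-12)) {
      stop("contract: detections must be sorted by descending score")
    }
  }
  if (nd == 0L) {
    return(list(tp = logical(0), matched_gt = integer(0),
                unmatched_gt = ng))
  }
  iou <- matrix(0, nd, ng)
  if (ng > 0L) {
    if (mode == "box") {
      D <- do.call(rbind, lapply(dets, function(d) as.numeric(d$box)))
      G <- do.call(rbind, lapply(gts, function(g) as.numeric(g$box)))
      iou <- box_iou_matrix(D, G)
    } else {
      dmask <- lapply(dets, function(d)
        contour_to_mask(d$contour, height, width))
      gmask <- lapply(gts, function(g)
        contour_to_mask(g$polygon, height, width))
      for (i in seq_len(nd)) for (j in seq_len(ng)) {
        iou[i, j] <- mask_iou(dmask[[i]], gmask[[j]])
      }
    }
  }
  claimed <- rep(FALSE, ng)
  tp <- logical(nd); matched <- rep(NA_integer_, nd)
  for (i in seq_len(nd)) {
    if (ng == 0L) break
    free <- which(!claimed)
    if (length(free) == 0L) break
    j <- free[which.max(iou[i, free])]
    if (iou[i, j] >= iou_threshold) {
      tp[i] <- TRUE; matched[i] <- j; claimed[j] <- TRUE
    }
  }
  list(tp = tp, matched_gt = matched, unmatched_gt = sum(!claimed))
}

#' 101-point interpolated average precision
#'
#' Pools per-detection true/false-positive flags across images, sorts them
#' by descending score and integrates the precision-recall staircase at the
#' 101 standard recall points 0, 0.01, ..., 1 using interpolated precision
#' (the maximum precision at any recall at least r).
#' @param match_results Data frame with columns `score` and `tp` (one row
#'   per detection, pooled across images).
#' @param n_gt Total number of ground-truth instances.
#' @return AP in `[0, 1]`; 0 when `n_gt` is 0.
#' @export
average_precision <- function(match_results, n_gt) {
  if (n_gt < 0) stop("parameter: n_gt must be >= 0")
  if (n_gt == 0L || nrow(match_results) == 0L) return(0)
  ord <- order(-match_results$score, seq_len(nrow(match_results)))
  tp <- match_results$tp[ord]
  ctp <- cumsum(tp); cfp <- cumsum(!tp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  rc_grid <- seq(0, 1, by = 0.01)
  # interpolated precision: running max from the right
  ip <- rev(cummax(rev(precision)))
  idx <- findInterval(rc_grid, recall, left.open = TRUE) + 1L
  p <- ifelse(idx <= length(ip), ip[idx], 0)
  mean(p)
}

#' Evaluate a prediction run against a dataset
#'
#' Computes per-class AP at IoU thresholds 0.50:0.05:0.95 and reports
#' AP (mean over thresholds and classes), AP50 and AP75 on the 0-100 scale.
#' @param predictions List of predictions: `image_id`, `category_id`,
#'   `score`, `box`, and for mask mode `contour`.
#' @param dataset A `coco_dataset`; ground truth is taken from the given
#'   split.
#' @param mode `"box"` or `"mask"`.
#' @param split Dataset split to evaluate against (default "val").
#' @param class_ids Restrict evaluation to these categories (default: all
#'   categories of the dataset).
#' @return An `eval_result` list: `AP`, `AP50`, `AP75`, `per_class`
#'   (data frame of per-class APs), `mode`.
#' @export
evaluate_run <- function(predictions, dataset, mode = "box", split = "val",
                         class_ids = NULL) {
  cat_ids <- vapply(dataset$categories, function(cc)
    as.integer(cc$id), integer(1))
  if (is.null(class_ids)) class_ids <- cat_ids
  bad <- setdiff(unique(vapply(predictions, function(p)
    as.integer(p$category_id), integer(1))), cat_ids)
  if (length(bad) > 0L) {
    stop(sprintf("data: unknown category id in predictions: %s",
                 paste(bad, collapse = ", ")))
  }
  ids <- dataset_image_ids(dataset, split = split)
  thresholds <- seq(0.5, 0.95, by = 0.05)
  per_class <- matrix(NA_real_, length(class_ids), length(thresholds),
                      dimnames = list(class_ids, sprintf("%.2f", thresholds)))
  for (ki in seq_along(class_ids)) {
    k <- class_ids[ki]
    n_gt <- 0L
    pooled <- vector("list", length(thresholds))
    for (id in ids) {
      im <- dataset_image(dataset, id)
      gts <- Filter(function(a) a$category_id == k,
                    dataset_annotations_for(dataset, id))
      gts <- lapply(gts, function(a)
        list(box = as.numeric(annotation_bbox(a)),
             polygon = annotation_polygon(a)))
      n_gt <- n_gt + length(gts)
      dets <- Filter(function(p) p$image_id == id && p$category_id == k,
                     predictions)
      if (length(dets) > 0L) {
        ord <- order(-det_scores(dets), seq_along(dets))
        dets <- dets[ord]
      }
      for (ti in seq_along(thresholds)) {
        mr <- match_detections(dets, gts, thresholds[ti], mode = mode,
                               height = im$height, width = im$width)
        if (length(dets) > 0L) {
          pooled[[ti]][[length(pooled[[ti]]) + 1L]] <-
            data.frame(score = det_scores(dets), tp = mr$tp)
        }
      }
    }
    for (ti in seq_along(thresholds)) {
      mrs <- if (length(pooled[[ti]]) > 0) do.call(rbind, pooled[[ti]])
      else data.frame(score = numeric(0), tp = logical(0))
      per_class[ki, ti] <- average_precision(mrs, n_gt)
    }
  }
  ap_per_class <- rowMeans(per_class)
  res <- list(
    AP = 100 * mean(per_class),
    AP50 = 100 * mean(per_class[, "0.50"]),
    AP75 = 100 * mean(per_class[, "0.75"]),
    per_class = data.frame(category_id = class_ids,
                           AP = 100 * ap_per_class,
                           AP50 = 100 * per_class[, "0.50"],
                           AP75 = 100 * per_class[, "0.75"]),
    thresholds = thresholds,
    mode = mode
  )
  class(res) <- "eval_result"
  res
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result (%s)>  AP %.1f  AP50 %.1f  AP75 %.1f\n",
              x$mode, x$AP, x$AP50, x$AP75))
  invisible(x)
}

#' Plain-text results table (Method / AP / AP50 / AP75)
#' @param results Named list of `eval_result` objects.
#' @return Character vector of table lines.
#' @export
format_eval_table <- function(results) {
  lines <- sprintf("%-24s %6s %6s %6s", "Method", "AP", "AP50", "AP75")
  for (nm in names(results)) {
    r <- results[[nm]]
    lines <- c(lines, sprintf("%-24s %6.1f %6.1f %6.1f",
                              nm, r$AP, r$AP50, r$AP75))
  }
  lines
}
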