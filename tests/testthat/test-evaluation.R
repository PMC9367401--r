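det <- function(box, score, cat = 1L, image_id = 1L) {
  list(box = box, score = score, category_id = cat, image_id = image_id)
}
gt <- function(box) list(box = box)

test_that("match_detections applies the score-greedy single-claim rule", {
  # perfect one-to-one
  dets <- list(det(c(0, 0, 10, 10), 0.9), det(c(20, 0, 30, 10), 0.8))
  gts <- list(gt(c(0, 0, 10, 10)), gt(c(20, 0, 30, 10)))
  mr <- match_detections(dets, gts, 0.5)
  expect_equal(mr$tp, c(TRUE, TRUE))
  expect_equal(mr$unmatched_gt, 0L)
  # IoU 0.6 case: TP at 0.5, FP at 0.75
  d1 <- list(det(c(0, 0, 10, 10), 0.9))
  g1 <- list(gt(c(0, 0, 10, 6)))
  expect_equal(box_iou(d1[[1]]$box, g1[[1]]$box), 0.6)
  expect_true(match_detections(d1, g1, 0.5)$tp)
  expect_false(match_detections(d1, g1, 0.75)$tp)
  # two detections on one gt: exactly one TP
  d2 <- list(det(c(0, 0, 10, 10), 0.9), det(c(1, 0, 11, 10), 0.8))
  mr2 <- match_detections(d2, list(gt(c(0, 0, 10, 10))), 0.5)
  expect_equal(sum(mr2$tp), 1L)
  expect_true(mr2$tp[1])
  # contract: unsorted input errors
  expect_error(match_detections(rev(d2), list(gt(c(0, 0, 10, 10))), 0.5),
               "contract")
})

test_that("average_precision integrates the 101-point interpolated staircase", {
  # all gts found, no false positives
  mr <- data.frame(score = c(0.9, 0.8), tp = c(TRUE, TRUE))
  expect_equal(average_precision(mr, 2L), 1.0)
  # no detections
  expect_equal(average_precision(data.frame(score = numeric(0),
                                            tp = logical(0)), 3L), 0)
  # 1 TP then 1 FP over 2 gts: precision 1 up to recall 0.5, then 0
  mr2 <- data.frame(score = c(0.9, 0.8), tp = c(TRUE, FALSE))
  # staircase by hand: interpolated precision is 1 for r <= 0.5 (51 of the
  # 101 recall points), 0 beyond
  expect_equal(average_precision(mr2, 2L), 51 / 101)
  expect_equal(average_precision(mr2, 2L), oracle_ap(c(0.9, 0.8),
                                                     c(TRUE, FALSE), 2L))
  # random tiny instances against the oracle
  set.seed(13)
  for (i in 1:30) {
    nd <- sample(1:5, 1); ng <- sample(1:3, 1)
    sc <- runif(nd); tp <- runif(nd) < 0.5
    got <- average_precision(data.frame(score = sc, tp = tp), ng)
    expect_equal(got, oracle_ap(sc, tp, ng), tolerance = 1e-12)
  }
})

test_that("AP is non-increasing in the matching threshold (AP50 >= AP75)", {
  set.seed(17)
  ds <- tiny_dataset()
  # noisy oracle detections: ground truth boxes with perturbations
  preds <- list()
  for (id in contourseg:::dataset_image_ids(ds, "val")) {
    for (a in contourseg:::dataset_annotations_for(ds, id)) {
      b <- as.numeric(contourseg:::annotation_bbox(a))
      w <- b[3] - b[1]; h <- b[4] - b[2]
      nb <- b + runif(4, -0.12, 0.12) * c(w, h, w, h)
      if (nb[3] <= nb[1] + 1 || nb[4] <= nb[2] + 1) nb <- b
      preds[[length(preds) + 1L]] <- det(nb, runif(1), a$category_id, id)
    }
  }
  ev <- evaluate_run(preds, ds, mode = "box", split = "val")
  expect_gte(ev$AP50, ev$AP75)
  expect_true(all(ev$per_class$AP50 >= ev$per_class$AP75 - 1e-9))
})

test_that("perfect predictions score 100 everywhere; removing a class lowers only its AP", {
  ds <- tiny_dataset()
  preds <- list()
  for (id in contourseg:::dataset_image_ids(ds, "val")) {
    for (a in contourseg:::dataset_annotations_for(ds, id)) {
      preds[[length(preds) + 1L]] <-
        list(box = contourseg:::annotation_bbox(a),
             contour = contourseg:::annotation_polygon(a),
             score = 1.0, category_id = a$category_id, image_id = id)
    }
  }
  ev <- evaluate_run(preds, ds, mode = "box", split = "val")
  expect_equal(ev$AP, 100)
  expect_equal(ev$AP50, 100)
  expect_equal(ev$AP75, 100)
  # mask mode with the exact ground-truth polygons is also perfect
  evm <- evaluate_run(preds, ds, mode = "mask", split = "val")
  expect_equal(evm$AP50, 100)
  # drop one class's predictions: only that class's AP falls
  drop_cls <- 2L
  preds2 <- Filter(function(p) p$category_id != drop_cls, preds)
  ev2 <- evaluate_run(preds2, ds, mode = "box", split = "val")
  expect_equal(ev2$per_class$AP[ev2$per_class$category_id == drop_cls], 0)
  keep <- ev2$per_class$category_id != drop_cls
  expect_equal(ev2$per_class$AP[keep], ev$per_class$AP[keep])
  expect_lt(ev2$AP, ev$AP)
  # unknown category id errors
  bad <- preds[1]; bad[[1]]$category_id <- 99L
  expect_error(evaluate_run(bad, ds), "data")
})

test_that("random boxes score near zero AP", {
  set.seed(23)
  ds <- tiny_dataset()
  preds <- list()
  for (id in contourseg:::dataset_image_ids(ds, "val")) {
    for (k in 1:3) {
      x0 <- runif(1, 0, 100); y0 <- runif(1, 0, 100)
      preds[[length(preds) + 1L]] <-
        det(c(x0, y0, x0 + runif(1, 5, 28), y0 + runif(1, 5, 28)),
            runif(1), sample(4L, 1), id)
    }
  }
  ev <- evaluate_run(preds, ds, mode = "box", split = "val")
  expect_lt(ev$AP, 5)
})

test_that("evaluation report table mirrors the Method/AP/AP50/AP75 layout", {
  r <- structure(list(AP = 57.6, AP50 = 85.1, AP75 = 65.0, mode = "box"),
                 class = "eval_result")
  tab <- format_eval_table(list(ours = r))
  expect_match(tab[1], "Method")
  expect_match(tab[2], "ours\\s+57.6\\s+85.1\\s+65.0")
})
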