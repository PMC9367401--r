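test_that("box_to_diamond connects the edge midpoints clockwise from the top", {
  d <- box_to_diamond(bbox(0, 0, 4, 2))
  expect_equal(unclass(d), cbind(x = c(2, 4, 2, 0), y = c(0, 1, 2, 1)))
  # shoelace identity: the diamond covers half the box, for any box
  set.seed(1)
  for (i in 1:20) {
    b <- bbox(runif(1, -50, 50), runif(1, -50, 50),
              runif(1, 51, 150), runif(1, 51, 150))
    area_box <- (b[3] - b[1]) * (b[4] - b[2])
    expect_equal(polygon_area(box_to_diamond(b)), area_box / 2)
  }
  expect_error(bbox(10, 10, 10, 20), "invalid-geometry")
})

test_that("resample_contour spaces vertices uniformly by arc length", {
  sq <- contour(rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)))
  r8 <- resample_contour(sq, 8)
  expect_equal(unclass(r8),
               cbind(x = c(0, 2, 4, 4, 4, 2, 0, 0),
                     y = c(0, 0, 0, 2, 4, 4, 4, 2)))
  # identity on an already-uniform contour at its own vertex count
  expect_equal(unclass(resample_contour(sq, 4)), unclass(sq))
  # irregular polygons against the dense-walk oracle
  set.seed(7)
  for (i in 1:5) {
    p <- random_simple_polygon(n = 5)
    got <- resample_contour(p, 128)
    expect_equal(unclass(got), oracle_resample(unclass(p), 128),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # equal arc-length spacing: consecutive vertices are L/128 apart along
    # the boundary, so each lies exactly at the oracle walk position
  }
  expect_error(resample_contour(sq, 2), "parameter")
})

test_that("resampling preserves the perimeter", {
  # exactly when the new spacing keeps the original vertices (the diamond's
  # equal sides divide evenly into 40)
  d <- box_to_diamond(bbox(3, 5, 47, 29))
  expect_equal(contour_perimeter(resample_contour(d, 40)),
               contour_perimeter(d), tolerance = 1e-6)
  # up to corner-cutting (vanishing with density) otherwise
  set.seed(3)
  for (i in 1:10) {
    p <- random_simple_polygon(n = sample(4:10, 1))
    r <- resample_contour(p, 400)
    expect_equal(contour_perimeter(r), contour_perimeter(p),
                 tolerance = 1e-2)
  }
})

test_that("build_octagon extends quarter edges from the extremes and clips at corners", {
  b <- bbox(0, 0, 8, 4)
  oc <- build_octagon(list(top = c(4, 0), leftmost = c(0, 2),
                           bottom = c(4, 4), rightmost = c(8, 2)), b)
  expect_equal(unclass(oc),
               cbind(x = c(2, 6, 8, 8, 6, 2, 0, 0),
                     y = c(0, 0, 1, 3, 4, 4, 3, 1)))
  # clipping: a top extreme near the corner clips its right endpoint
  oc2 <- build_octagon(list(top = c(7.5, 0), leftmost = c(0, 2),
                            bottom = c(4, 4), rightmost = c(8, 2)), b)
  expect_equal(as.numeric(oc2[2, ]), c(8, 0))
  # octagon never leaves the box
  set.seed(11)
  for (i in 1:25) {
    bb <- bbox(0, 0, runif(1, 4, 60), runif(1, 4, 60))
    ex <- list(top = c(runif(1, 0, bb[3]), 0),
               leftmost = c(0, runif(1, 0, bb[4])),
               bottom = c(runif(1, 0, bb[3]), bb[4]),
               rightmost = c(bb[3], runif(1, 0, bb[4])))
    oc <- build_octagon(ex, bb)
    expect_true(all(oc[, 1] >= bb[1] - 1e-9 & oc[, 1] <= bb[3] + 1e-9))
    expect_true(all(oc[, 2] >= bb[2] - 1e-9 & oc[, 2] <= bb[4] + 1e-9))
  }
  expect_error(
    build_octagon(list(top = c(4, -40), leftmost = c(0, 2),
                       bottom = c(4, 4), rightmost = c(8, 2)), b, tol = 1),
    "invalid-geometry")
})

test_that("octagon from edge midpoints is invariant under 180-degree rotation", {
  b <- bbox(2, 3, 14, 11)
  mid <- list(top = c(8, 3), leftmost = c(2, 7),
              bottom = c(8, 11), rightmost = c(14, 7))
  oc <- unclass(build_octagon(mid, b))
  ctr <- c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
  rot <- sweep(-sweep(oc, 2, ctr), 2, ctr, `+`)    # rotate 180 about center
  # the rotated vertex set maps onto the original vertex set
  for (i in seq_len(nrow(rot))) {
    d <- sqrt(rowSums(sweep(oc, 2, rot[i, ])^2))
    expect_lt(min(d), 1e-9)
  }
})

test_that("contour_to_mask matches the ray-casting oracle", {
  # exact cover of a pixel block
  m <- contour_to_mask(contour(rbind(c(1, 1), c(5, 1), c(5, 5), c(1, 5))),
                       8, 8)
  expect_equal(sum(m), 16)
  expect_true(all(m[2:5, 2:5]))
  # fully outside the raster
  far <- contour(rbind(c(100, 100), c(110, 100), c(110, 110)))
  expect_false(any(contour_to_mask(far, 16, 16)))
  # random polygons vs the per-pixel oracle
  set.seed(5)
  for (i in 1:8) {
    p <- random_simple_polygon(n = sample(5:12, 1), cx = 16, cy = 16,
                               rmin = 3, rmax = 14)
    expect_identical(contour_to_mask(p, 32, 32), oracle_mask(p, 32, 32))
  }
  expect_error(contour_to_mask(far, 0, 16), "parameter")
})

test_that("mask_iou counts pixels of intersection over union", {
  a <- matrix(FALSE, 6, 6); a[2:3, 2:3] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 6, 6); b[5:6, 5:6] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  c2 <- matrix(FALSE, 6, 6); c2[2:3, 3:4] <- TRUE   # overlap = 1x2 strip
  expect_equal(mask_iou(a, c2), 2 / 6)
  expect_equal(mask_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), 0)
  expect_error(mask_iou(a, matrix(FALSE, 5, 6)), "parameter")
})

test_that("box_iou is exact rectangle arithmetic, zero for touching boxes", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 2 / 6)
  expect_equal(box_iou(c(0, 0, 2, 2), c(2, 0, 4, 2)), 0)
  # symmetry + bounds on random pairs; agreement with mask-based IoU on
  # integer-aligned boxes
  set.seed(9)
  for (i in 1:25) {
    a <- sort(sample(0:20, 2)); b <- sort(sample(0:20, 2))
    a2 <- sort(sample(0:20, 2)); b2 <- sort(sample(0:20, 2))
    if (a[1] == a[2] || b[1] == b[2] || a2[1] == a2[2] || b2[1] == b2[2]) next
    A <- c(a[1], b[1], a[2], b[2]); B <- c(a2[1], b2[1], a2[2], b2[2])
    expect_equal(box_iou(A, B), box_iou(B, A))
    expect_gte(box_iou(A, B), 0); expect_lte(box_iou(A, B), 1)
    ma <- contour_to_mask(contour(rbind(c(A[1], A[2]), c(A[3], A[2]),
                                        c(A[3], A[4]), c(A[1], A[4]))), 20, 20)
    mb <- contour_to_mask(contour(rbind(c(B[1], B[2]), c(B[3], B[2]),
                                        c(B[3], B[4]), c(B[1], B[4]))), 20, 20)
    expect_equal(box_iou(A, B), mask_iou(ma, mb), tolerance = 1e-12)
  }
})

test_that("clip_polygon truncates at the frame and preserves inside polygons", {
  sq <- contour(rbind(c(2, 2), c(6, 2), c(6, 6), c(2, 6)))
  expect_equal(polygon_area(clip_polygon(sq, bbox(0, 0, 8, 8))), 16)
  half <- clip_polygon(sq, bbox(0, 0, 4, 8))
  expect_equal(polygon_area(half), 8)
  expect_null(clip_polygon(sq, bbox(10, 10, 20, 20)))
})

test_that("COCO round trips preserve boxes and polygons", {
  b <- bbox(3.5, 2, 10, 8)
  expect_equal(as.numeric(as_bbox(bbox_from_xywh(bbox_to_xywh(b)))),
               as.numeric(b))
  p <- random_simple_polygon(n = 7)
  expect_equal(unclass(coco_to_contour(contour_to_coco(p))), unclass(p))
})

test_that("diamond resampled to 40 vertices keeps its perimeter and corners", {
  b <- bbox(10, 20, 90, 60)
  d <- box_to_diamond(b)
  r <- resample_contour(d, 40)
  expect_equal(nrow(r), 40L)
  expect_equal(contour_perimeter(r), contour_perimeter(d), tolerance = 1e-6)
  # the four original midpoints survive at indices 1, 11, 21, 31
  expect_equal(unclass(r[c(1, 11, 21, 31), ]), unclass(d),
               tolerance = 1e-9)
})
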