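#' @title Contour and box geometry
#' @description Deterministic geometric primitives used throughout the
#'   pipeline: boxes, cyclic contours, diamond/octagon initial contours,
#'   uniform arc-length resampling, polygon rasterization and IoU.
#'
#' Coordinate convention: continuous pixel coordinates with the origin at the
#' top-left corner of pixel (1,1); x grows rightward, y grows downward; the
#' center of the pixel in raster row r, column c is (c - 0.5, r - 0.5).
#' Boxes are half-open regions `[x0, x1) x [y0, y1)`. A contour is an n x 2
#' numeric matrix of vertices (columns x, y), cyclic by convention (the last
#' vertex connects back to the first; the first vertex is never duplicated).
#' @name geometry
NULL

#' Construct an axis-aligned bounding box
#'
#' @param x0,y0,x1,y1 Corner coordinates in pixels; `x0 < x1`, `y0 < y1`.
#' @return An object of class `bbox`: numeric vector `c(x0, y0, x1, y1)`.
#' @export
bbox <- function(x0, y0, x1, y1) {
  b <- c(as.numeric(x0), as.numeric(y0), as.numeric(x1), as.numeric(y1))
  if (any(!is.finite(b))) {
    stop("invalid-geometry: box coordinates must be finite")
  }
  if (b[3] <= b[1] || b[4] <= b[2]) {
    stop("invalid-geometry: box must have strictly positive width and height")
  }
  class(b) <- "bbox"
  b
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox [%.3f, %.3f] x [%.3f, %.3f] (w=%.3f, h=%.3f)>\n",
              x[1], x[3], x[2], x[4], x[3] - x[1], x[4] - x[2]))
  invisible(x)
}

as_bbox <- function(b) {
  if (inherits(b, "bbox")) return(b)
  b <- as.numeric(b)
  bbox(b[1], b[2], b[3], b[4])
}

bbox_wh <- function(b) c(b[3] - b[1], b[4] - b[2])

#' Convert between corner-form and COCO `[x, y, width, height]` boxes
#'
#' COCO annotations store boxes as `[x, y, w, h]`; internally corner form
#' `(x0, y0, x1, y1)` is used.
#' @param xywh Numeric length-4 vector `[x, y, w, h]`.
#' @return `bbox_from_xywh`: a [bbox()]; `bbox_to_xywh`: numeric `[x, y, w, h]`.
#' @export
bbox_from_xywh <- function(xywh) {
  bbox(xywh[1], xywh[2], xywh[1] + xywh[3], xywh[2] + xywh[4])
}

#' @rdname bbox_from_xywh
#' @param b A [bbox()].
#' @export
bbox_to_xywh <- function(b) {
  b <- as_bbox(b)
  as.numeric(c(b[1], b[2], b[3] - b[1], b[4] - b[2]))
}

#' Create a contour from vertex coordinates
#'
#' @param xy An n x 2 numeric matrix (columns x, y), n >= 3. The contour is
#'   cyclic: the last vertex connects to the first.
#' @return An object of class `contour` (n x 2 matrix).
#' @export
contour <- function(xy) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L || nrow(xy) < 3L) {
    stop("invalid-geometry: a contour needs an n x 2 matrix with n >= 3")
  }
  if (any(!is.finite(xy))) stop("invalid-geometry: non-finite contour vertex")
  dimnames(xy) <- list(NULL, c("x", "y"))
  class(xy) <- c("contour", "matrix", "array")
  xy
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour, %d vertices, perimeter %.3f, area %.3f>\n",
              nrow(x), contour_perimeter(x), polygon_area(x)))
  invisible(x)
}

as_contour <- function(xy) if (inherits(xy, "contour")) xy else contour(xy)

#' Signed and absolute polygon area (shoelace formula)
#'
#' With image coordinates (y downward) a clockwise-on-screen contour has
#' positive signed area.
#' @param xy Contour or n x 2 matrix.
#' @return `polygon_area`: absolute area; `polygon_signed_area`: signed.
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' @rdname polygon_area
#' @export
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Perimeter of a closed polygonal contour
#' @param xy Contour or n x 2 matrix.
#' @export
contour_perimeter <- function(xy) {
  d <- rbind(xy[-1, , drop = FALSE], xy[1, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

#' Force clockwise orientation (image coordinates)
#' @param xy Contour.
#' @export
ensure_clockwise <- function(xy) {
  xy <- as_contour(xy)
  if (polygon_signed_area(xy) < 0) {
    xy <- contour(xy[rev(seq_len(nrow(xy))), , drop = FALSE])
  }
  xy
}

contour_centroid <- function(xy) colMeans(xy[, 1:2, drop = FALSE])

#' Diamond contour from a bounding box
#'
#' Connects the midpoints of the four box edges, giving the 4-vertex diamond
#' that seeds extreme-point prediction. Vertices are returned clockwise
#' starting from the top-edge midpoint: top, right, bottom, left.
#' @param box A [bbox()].
#' @return A 4-vertex [contour()].
#' @export
box_to_diamond <- function(box) {
  b <- as_bbox(box)
  cx <- (b[1] + b[3]) / 2
  cy <- (b[2] + b[4]) / 2
  contour(rbind(
    c(cx, b[2]),   # top edge midpoint
    c(b[3], cy),   # right
    c(cx, b[4]),   # bottom
    c(b[1], cy)    # left
  ))
}

#' Resample a contour to n vertices uniformly spaced by arc length
#'
#' Walks the closed polygonal boundary and places `n` vertices at equal
#' arc-length intervals, starting at the original first vertex (no phase
#' optimization). The perimeter is preserved up to chord shortening; for
#' `n` at least the input vertex count and commensurate spacing the original
#' vertices are reproduced exactly.
#' @param xy Contour.
#' @param n Number of output vertices, >= 3.
#' @return An n x 2 [contour()].
#' @export
resample_contour <- function(xy, n) {
  xy <- as_contour(xy)
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("parameter: n must be an integer >= 3")
  closed <- rbind(xy, xy[1, , drop = FALSE])
  seg <- diff(closed)
  seglen <- sqrt(rowSums(seg^2))
  L <- sum(seglen)
  if (L <= 0) stop("invalid-geometry: contour has zero perimeter")
  cum <- c(0, cumsum(seglen))
  target <- (seq_len(n) - 1) * L / n
  # segment index for each target arc length
  idx <- findInterval(target, cum, rightmost.closed = TRUE)
  idx[idx > nrow(xy)] <- nrow(xy)
  # skip zero-length segments: findInterval already lands past them
  t <- (target - cum[idx]) / seglen[idx]
  t[!is.finite(t)] <- 0
  out <- closed[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
  contour(out)
}

#' Extreme points of a contour
#'
#' The top-most, left-most, bottom-most and right-most vertices (ties broken
#' by first occurrence). For densely sampled analytic shapes this is the
#' exact ground truth used to supervise extreme-point prediction.
#' @param xy Contour.
#' @return A list with elements `top`, `leftmost`, `bottom`, `rightmost`,
#'   each a length-2 numeric `(x, y)`.
#' @export
contour_extremes <- function(xy) {
  xy <- as_contour(xy)
  list(
    top       = xy[which.min(xy[, 2]), ],
    leftmost  = xy[which.min(xy[, 1]), ],
    bottom    = xy[which.max(xy[, 2]), ],
    rightmost = xy[which.max(xy[, 1]), ]
  )
}

#' Octagon contour from four extreme points and a box
#'
#' From each extreme point, two octagon vertices are created by extending a
#' quarter of the corresponding box edge length in both directions along that
#' edge (box width for the horizontal top/bottom edges, box height for the
#' vertical left/right edges), clipping at the box corners so the octagon
#' never leaves the box. The 8 vertices are returned clockwise starting from
#' the top extreme's left endpoint.
#'
#' Extreme points are first projected onto their corresponding box edge
#' (x clamped to the edge for top/bottom, y clamped for left/right); a point
#' farther outside the box than `tol` raises an invalid-geometry error.
#' @param extremes List with `top`, `leftmost`, `bottom`, `rightmost` points
#'   (as produced by [contour_extremes()]).
#' @param box A [bbox()].
#' @param tol Maximum allowed distance of an extreme point outside the box
#'   region; defaults to half the box half-perimeter, `0.5 * (w + h)`.
#' @return An 8-vertex [contour()].
#' @export
build_octagon <- function(extremes, box, tol = NULL) {
  b <- as_bbox(box)
  w <- b[3] - b[1]; h <- b[4] - b[2]
  if (is.null(tol)) tol <- 0.5 * (w + h)
  pts <- lapply(extremes[c("top", "leftmost", "bottom", "rightmost")],
                function(p) as.numeric(p)[1:2])
  if (any(vapply(pts, function(p) any(!is.finite(p)), logical(1)))) {
    stop("invalid-geometry: non-finite extreme point")
  }
  out_dist <- function(p) {
    dx <- max(b[1] - p[1], p[1] - b[3], 0)
    dy <- max(b[2] - p[2], p[2] - b[4], 0)
    sqrt(dx^2 + dy^2)
  }
  if (any(vapply(pts, out_dist, numeric(1)) > tol)) {
    stop("invalid-geometry: extreme point lies too far outside the box")
  }
  clampx <- function(x) min(max(x, b[1]), b[3])
  clampy <- function(y) min(max(y, b[2]), b[4])
  xt <- clampx(pts$top[1])       # top extreme projected on edge y = y0
  yl <- clampy(pts$leftmost[2])  # left extreme on edge x = x0
  xb <- clampx(pts$bottom[1])    # bottom extreme on edge y = y1
  yr <- clampy(pts$rightmost[2]) # right extreme on edge x = x1
  ext_w <- w / 4; ext_h <- h / 4
  contour(rbind(
    c(clampx(xt - ext_w), b[2]),  # top edge, left endpoint
    c(clampx(xt + ext_w), b[2]),  # top edge, right endpoint
    c(b[3], clampy(yr - ext_h)),  # right edge, upper
    c(b[3], clampy(yr + ext_h)),  # right edge, lower
    c(clampx(xb + ext_w), b[4]),  # bottom edge, right endpoint
    c(clampx(xb - ext_w), b[4]),  # bottom edge, left endpoint
    c(b[1], clampy(yl + ext_h)),  # left edge, lower
    c(b[1], clampy(yl - ext_h))   # left edge, upper
  ))
}

#' Rasterize a polygon to a binary mask
#'
#' Marks every pixel whose center falls inside the polygon under the even-odd
#' rule; self-intersecting polygons rasterize under the same rule without
#' error. Pixel centers are at `(c - 0.5, r - 0.5)` for raster row r,
#' column c.
#' @param xy Contour (any polygon, need not be simple).
#' @param height,width Raster dimensions in pixels.
#' @return A `height x width` logical matrix.
#' @export
contour_to_mask <- function(xy, height, width) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L) {
    stop("parameter: raster dimensions must be positive integers")
  }
  xy <- as_contour(xy)
  px <- rep(seq_len(width) - 0.5, each = height)
  py <- rep(seq_len(height) - 0.5, times = width)
  inside <- rep(FALSE, height * width)
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  for (i in seq_len(n)) {
    if (y[i] == yn[i]) next
    crosses <- (y[i] <= py) != (yn[i] <= py)
    if (!any(crosses)) next
    xint <- x[i] + (py - y[i]) * (xn[i] - x[i]) / (yn[i] - y[i])
    inside <- xor(inside, crosses & (px < xint))
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Intersection-over-union of two binary masks
#'
#' `|A & B| / |A | B|`; 0 when the union is empty.
#' @param a,b Logical matrices of identical dimensions.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("parameter: mask dimensions must match")
  }
  uni <- sum(a | b)
  if (uni == 0) return(0)
  sum(a & b) / uni
}

#' Intersection-over-union of two boxes
#'
#' Area of the intersection rectangle over the area of the union; 0 for
#' disjoint or merely touching boxes.
#' @param a,b Boxes ([bbox()] or length-4 corner vectors).
#' @return IoU in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  a <- as_bbox(a); b <- as_bbox(b)
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  areas <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2])
  inter / (areas - inter)
}

# Vectorized IoU between an m x 4 and an n x 4 matrix of corner-form boxes.
box_iou_matrix <- function(A, B) {
  m <- nrow(A); n <- nrow(B)
  ix0 <- pmax(matrix(A[, 1], m, n), matrix(B[, 1], m, n, byrow = TRUE))
  iy0 <- pmax(matrix(A[, 2], m, n), matrix(B[, 2], m, n, byrow = TRUE))
  ix1 <- pmin(matrix(A[, 3], m, n), matrix(B[, 3], m, n, byrow = TRUE))
  iy1 <- pmin(matrix(A[, 4], m, n), matrix(B[, 4], m, n, byrow = TRUE))
  iw <- pmax(ix1 - ix0, 0); ih <- pmax(iy1 - iy0, 0)
  inter <- iw * ih
  areaA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  areaB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  uni <- matrix(areaA, m, n) + matrix(areaB, m, n, byrow = TRUE) - inter
  out <- inter / uni
  out[uni <= 0] <- 0
  out
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping against the four half-planes of the rectangle.
#' Used to truncate instances at the image border.
#' @param xy Contour.
#' @param rect A [bbox()] clip region.
#' @return A [contour()], or `NULL` if the polygon is entirely outside.
#' @export
clip_polygon <- function(xy, rect) {
  rect <- as_bbox(rect)
  pts <- as_contour(xy)[, 1:2, drop = FALSE]
  clip_edge <- function(pts, inside, intersect) {
    if (nrow(pts) == 0) return(pts)
    n <- nrow(pts)
    out <- vector("list", 2L * n)
    k <- 0L
    prev <- pts[n, ]
    prev_in <- inside(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; cur_in <- inside(cur)
      if (cur_in) {
        if (!prev_in) { k <- k + 1L; out[[k]] <- intersect(prev, cur) }
        k <- k + 1L; out[[k]] <- cur
      } else if (prev_in) {
        k <- k + 1L; out[[k]] <- intersect(prev, cur)
      }
      prev <- cur; prev_in <- cur_in
    }
    if (k == 0L) return(pts[0, , drop = FALSE])
    do.call(rbind, out[seq_len(k)])
  }
  ix <- function(p, q, t) p + (q - p) * t
  pts <- clip_edge(pts, function(p) p[1] >= rect[1],
                   function(p, q) ix(p, q, (rect[1] - p[1]) / (q[1] - p[1])))
  pts <- clip_edge(pts, function(p) p[1] <= rect[3],
                   function(p, q) ix(p, q, (rect[3] - p[1]) / (q[1] - p[1])))
  pts <- clip_edge(pts, function(p) p[2] >= rect[2],
                   function(p, q) ix(p, q, (rect[2] - p[2]) / (q[2] - p[2])))
  pts <- clip_edge(pts, function(p) p[2] <= rect[4],
                   function(p, q) ix(p, q, (rect[4] - p[2]) / (q[2] - p[2])))
  # drop consecutive duplicates introduced by clipping
  if (nrow(pts) >= 2) {
    d <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE]) - pts
    keep <- rowSums(d^2) > 1e-18
    pts <- pts[keep, , drop = FALSE]
  }
  if (nrow(pts) < 3) return(NULL)
  contour(pts)
}

#' Tight bounding box of a contour
#' @param xy Contour.
#' @return A [bbox()].
#' @export
contour_bbox <- function(xy) {
  xy <- as_contour(xy)
  bbox(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
}

#' Serialize / parse COCO polygon segmentations
#'
#' COCO stores one polygon as a flat list `[x1, y1, x2, y2, ...]`.
#' @param xy Contour.
#' @return `contour_to_coco`: flat numeric vector; `coco_to_contour`: a
#'   [contour()].
#' @export
contour_to_coco <- function(xy) as.numeric(t(as_contour(xy)[, 1:2]))

#' @rdname contour_to_coco
#' @param flat Flat numeric vector of interleaved x, y coordinates.
#' @export
coco_to_contour <- function(flat) {
  contour(matrix(as.numeric(flat), ncol = 2, byrow = TRUE))
}

# TRUE if the closed polygon has no two properly crossing edges (O(n^2)).
contour_is_simple <- function(xy) {
  xy <- as_contour(xy)
  n <- nrow(xy)
  P <- rbind(xy, xy[1, ])
  seg_cross <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (seg_cross(P[i, ], P[i + 1, ], P[j, ], P[j + 1, ])) return(FALSE)
    }
  }
  TRUE
}
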