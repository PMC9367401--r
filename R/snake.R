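#' @title Deep-snake contour deformation
#' @description Learning-based active contour: circular convolution over the
#'   cyclic vertex graph, extreme-point prediction from a diamond contour,
#'   octagon initialization, and iterative per-vertex offset regression.
#' @name snake
NULL

#' Snake hyperparameter configuration
#'
#' Defaults: 40 points sampled on the diamond contour (the extra points
#' provide context for extreme-point prediction), N = 128 points on the
#' octagon contour with N offsets output per deformation round, and 3
#' deformation iterations (large offsets are hard to regress in one step;
#' iterating splits the move into manageable pieces).
#'
#' @param n_diamond Points sampled on the diamond contour (multiple of 4).
#' @param n_contour N, points sampled on the octagon contour (>= 8).
#' @param iterations Deformation rounds (>= 1).
#' @param kernel_size Odd circular-convolution kernel width.
#' @param feature_dim Appearance channels sampled from the feature pyramid
#'   (stride-2 and stride-4 levels concatenated).
#' @param hidden_dim Width of the circular-convolution layers.
#' @return A list of class `snake_config`.
#' @export
snake_config <- function(n_diamond = 40L, n_contour = 128L, iterations = 3L,
                         kernel_size = 3L, feature_dim = 48L,
                         hidden_dim = 64L) {
  n_diamond <- as.integer(n_diamond); n_contour <- as.integer(n_contour)
  iterations <- as.integer(iterations); kernel_size <- as.integer(kernel_size)
  if (n_diamond < 4L || n_diamond %% 4L != 0L) {
    stop("parameter: n_diamond must be a positive multiple of 4")
  }
  if (n_contour < 8L) stop("parameter: n_contour must be >= 8")
  if (iterations < 1L) stop("parameter: iterations must be >= 1")
  if (kernel_size %% 2L == 0L) stop("parameter: kernel_size must be odd")
  structure(list(n_diamond = n_diamond, n_contour = n_contour,
                 iterations = iterations, kernel_size = kernel_size,
                 feature_dim = as.integer(feature_dim),
                 hidden_dim = as.integer(hidden_dim)),
            class = "snake_config")
}

# ---- circular convolution ------------------------------------------------

cyc_plan <- function(n, k) {
  half <- (k - 1L) %/% 2L
  idx <- matrix(0L, n, k)
  base <- seq_len(n) - 1L
  for (j in seq_len(k)) {
    idx[, j] <- ((base + (j - 1L) - half) %% n) + 1L
  }
  list(n = n, k = k, idx_vec = as.vector(idx))
}

#' Circular convolution on a cyclic vertex sequence
#'
#' Computes `out[i] = sum_j kernel[j] %*% features[(i + j - (k-1)/2 - 1) mod n + 1]`
#' with cyclic index wrapping, so the contour has no boundary: the operation
#' respects the cycle-graph topology of a closed contour.
#'
#' @param features n x d numeric matrix of per-vertex features.
#' @param kernel k x d x d' numeric array (k odd, k <= n); `kernel[j, , ]`
#'   maps the feature of the j-th tap to the output.
#' @param bias Optional length-d' bias.
#' @return n x d' matrix.
#' @export
circular_conv <- function(features, kernel, bias = NULL) {
  features <- as.matrix(features)
  dk <- dim(kernel)
  if (length(dk) != 3L) stop("parameter: kernel must be a k x d x d' array")
  k <- dk[1]
  if (k %% 2L == 0L) stop("parameter: kernel width k must be odd")
  n <- nrow(features); d <- ncol(features)
  if (d != dk[2]) stop("parameter: feature dimension mismatch")
  if (n < k) stop("parameter: need at least k vertices")
  plan <- cyc_plan(n, k)
  out <- cconv_forward(features, matrix(kernel, k * d, dk[3]), plan)$out
  if (!is.null(bias)) out <- sweep(out, 2, bias, `+`)
  out
}

# Internal fast path: weight matrix rows ordered (tap fast, channel slow).
cconv_forward <- function(F, Wmat, plan) {
  patches <- F[plan$idx_vec, , drop = FALSE]      # (n*k) x d
  dim(patches) <- NULL
  patches <- matrix(patches, plan$n, plan$k * ncol(F))
  list(out = patches %*% Wmat, patches = patches)
}

cconv_backward <- function(dOut, Wmat, plan, patches, d_in) {
  gW <- crossprod(patches, dOut)
  dPatch <- dOut %*% t(Wmat)                      # n x (k*d)
  dim(dPatch) <- NULL
  dPatch <- matrix(dPatch, plan$n * plan$k, d_in)
  acc <- rowsum(dPatch, group = plan$idx_vec, reorder = FALSE)
  dF <- matrix(0, plan$n, d_in)
  dF[as.integer(rownames(acc)), ] <- acc
  list(dF = dF, gW = gW)
}

# ---- snake block ---------------------------------------------------------

# Two circular-conv layers, a fused global feature (channel-wise max over
# vertices broadcast back to every vertex), and a per-vertex 2-channel
# offset head. The global max keeps the block equivariant to cyclic shifts.
snake_block_init <- function(d_in, hidden = 64L, k = 3L) {
  list(
    cc1 = list(W = nn_init_matrix(k * d_in, hidden), b = numeric(hidden)),
    cc2 = list(W = nn_init_matrix(k * hidden, hidden), b = numeric(hidden)),
    fc1 = nn_init_dense(2L * hidden, hidden),
    head = nn_init_dense(hidden, 2L, scale = 0.01),
    k = k, d_in = d_in, hidden = hidden
  )
}

snake_block_forward <- function(params, vf) {
  n <- nrow(vf)
  if (ncol(vf) != params$d_in) stop("parameter: feature-dimension mismatch")
  plan1 <- cyc_plan(n, params$k)
  f1 <- cconv_forward(vf, params$cc1$W, plan1)
  a1 <- relu(sweep(f1$out, 2, params$cc1$b, `+`))
  f2 <- cconv_forward(a1, params$cc2$W, plan1)
  a2 <- relu(sweep(f2$out, 2, params$cc2$b, `+`))
  gidx <- max.col(t(a2), ties.method = "first")   # argmax vertex per channel
  g <- a2[cbind(gidx, seq_len(ncol(a2)))]
  z <- cbind(a2, matrix(g, n, length(g), byrow = TRUE))
  a3 <- relu(dense_forward(z, params$fc1))
  out <- dense_forward(a3, params$head)
  list(out = out,
       cache = list(vf = vf, plan = plan1, p1 = f1$patches, a1 = a1,
                    p2 = f2$patches, a2 = a2, gidx = gidx, z = z, a3 = a3))
}

snake_block_backward <- function(params, cache, dOut, need_dvf = TRUE) {
  hb <- dense_backward(dOut, cache$a3, params$head)
  d3 <- relu_backward(hb$dX, cache$a3)
  fb <- dense_backward(d3, cache$z, params$fc1)
  h <- params$hidden
  dz <- fb$dX
  da2 <- dz[, seq_len(h), drop = FALSE]
  dg <- colSums(dz[, h + seq_len(h), drop = FALSE])
  da2[cbind(cache$gidx, seq_len(h))] <-
    da2[cbind(cache$gidx, seq_len(h))] + dg
  da2 <- relu_backward(da2, cache$a2)
  b2 <- cconv_backward(da2, params$cc2$W, cache$plan, cache$p2, h)
  da1 <- relu_backward(b2$dF, cache$a1)
  b1 <- cconv_backward(da1, params$cc1$W, cache$plan, cache$p1, params$d_in)
  list(
    grads = list(
      cc1 = list(W = b1$gW, b = colSums(da1)),
      cc2 = list(W = b2$gW, b = colSums(da2)),
      fc1 = fb$grad,
      head = hb$grad
    ),
    dvf = if (need_dvf) b1$dF else NULL
  )
}

# Offsets for a contour given parameters (exported-facing deterministic op).
snake_block_offsets <- function(params, vf) snake_block_forward(params, vf)$out

# ---- vertex features -----------------------------------------------------

# Appearance features bilinearly sampled at vertex coordinates from every
# pyramid level, concatenated with vertex coordinates relative to the
# contour centroid, scale-normalized by the RMS centroid distance (so the
# geometric channels are O(1) regardless of object size).
vertex_features <- function(fg, xy) {
  xy <- unclass(xy)[, 1:2, drop = FALSE]
  apps <- vector("list", length(fg$levels))
  plans <- vector("list", length(fg$levels))
  for (li in seq_along(fg$levels)) {
    lv <- fg$levels[[li]]
    plans[[li]] <- bilinear_plan(xy[, 1], xy[, 2], lv$Hf, lv$Wf, lv$stride)
    apps[[li]] <- bilinear_sample(lv$grid, plans[[li]])
  }
  ctr <- colMeans(xy)
  rel <- sweep(xy, 2, ctr)
  s <- sqrt(mean(rowSums(rel^2)))
  if (!is.finite(s) || s < 1e-9) s <- 1
  list(vf = cbind(do.call(cbind, apps), rel / s), plans = plans)
}

# Scatter appearance-feature gradients back into each pyramid level's grid
# accumulator. `d_app` has the concatenated level columns.
vf_backward_scatter <- function(d_app, fg, plans, acc) {
  col0 <- 0L
  for (li in seq_along(fg$levels)) {
    C <- ncol(fg$levels[[li]]$grid)
    dl <- d_app[, col0 + seq_len(C), drop = FALSE]
    acc[[li]] <- acc[[li]] +
      bilinear_backward(dl, fg$levels[[li]]$grid, plans[[li]])
    col0 <- col0 + C
  }
  acc
}

# ---- snake model ---------------------------------------------------------

snake_arch <- function(cfg) {
  list(c(3, 2, 3, 16), c(3, 2, 16, 32), c(3, 1, 32, 32))
}

# Two-level feature pyramid from a backbone cache: the stride-2 first-layer
# activation (fine localization) and the stride-4 final activation (context).
snake_levels_from_cache <- function(bb) {
  list(
    feature_grid(bb$acts[[1]], bb$plans[[1]]$Ho, bb$plans[[1]]$Wo, 2L),
    feature_grid(bb$out, bb$out_h, bb$out_w, 4L)
  )
}

#' Initialize a snake model
#'
#' The model couples a small strided convolutional feature extractor
#' (stride 4) with two snake blocks: one predicting offsets from the diamond
#' contour to the four extreme points, one regressing per-vertex offsets of
#' the octagon contour toward the object boundary.
#' @param cfg A [snake_config()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `snake_model`.
#' @export
snake_init <- function(cfg = snake_config(), seed = 1L) {
  set.seed(seed)
  d_in <- cfg$feature_dim + 2L
  structure(list(
    cfg = cfg,
    feat = conv_stack_init(snake_arch(cfg)),
    ex_block = snake_block_init(d_in, cfg$hidden_dim, cfg$kernel_size),
    de_block = snake_block_init(d_in, cfg$hidden_dim, cfg$kernel_size)
  ), class = "snake_model")
}

#' Compute the snake feature grid of an image
#' @param model A `snake_model`.
#' @param img `[H, W, 3]` numeric array in `[0, 1]`.
#' @return A `snake_features` feature pyramid.
#' @export
snake_features <- function(model, img) {
  H <- dim(img)[1]; W <- dim(img)[2]
  arch <- snake_arch(model$cfg)
  fw <- conv_stack_forward(model$feat, image_to_matrix(img), arch, H, W)
  structure(list(levels = snake_levels_from_cache(fw)),
            class = "snake_features")
}

# Indices of the four original diamond midpoints in the resampled diamond.
# The diamond's four sides have equal length, so uniform arc-length
# resampling to n (multiple of 4) keeps the corners at 1, n/4+1, ...
diamond_anchor_idx <- function(n) as.integer(1L + (0:3) * (n %/% 4L))

#' Predict the four extreme points of an object from its box
#'
#' Builds the diamond contour from the box, resamples it to
#' `cfg$n_diamond` points for context, runs the extreme-point snake block,
#' and reads the predicted offsets at the four original edge midpoints.
#' Offsets are added to the midpoints: top, rightmost, bottom, leftmost.
#' @param model A `snake_model`.
#' @param box A [bbox()] (must lie inside the feature grid's image).
#' @param fg A `snake_features` feature pyramid.
#' @return List with `top`, `leftmost`, `bottom`, `rightmost` points.
#' @export
predict_extreme_points <- function(model, box, fg) {
  b <- as_bbox(box)
  lv <- fg$levels[[1]]
  img_w <- lv$Wf * lv$stride; img_h <- lv$Hf * lv$stride
  if (b[1] < -1e-6 || b[2] < -1e-6 || b[3] > img_w + 1e-6 ||
      b[4] > img_h + 1e-6) {
    stop("invalid-geometry: box outside the feature grid")
  }
  dia <- resample_contour(box_to_diamond(b), model$cfg$n_diamond)
  vf <- vertex_features(fg, dia)
  off <- snake_block_forward(model$ex_block, vf$vf)$out
  ai <- diamond_anchor_idx(model$cfg$n_diamond)
  pts <- dia[ai, , drop = FALSE] + off[ai, , drop = FALSE]
  list(top = pts[1, ], rightmost = pts[2, ],
       bottom = pts[3, ], leftmost = pts[4, ])
}

# Clamp extreme points into the box rectangle (predictions may drift; the
# octagon construction is defined only on the box boundary).
project_extremes <- function(ex, box) {
  b <- as_bbox(box)
  cl <- function(p) c(min(max(p[1], b[1]), b[3]), min(max(p[2], b[2]), b[4]))
  lapply(ex, cl)
}

#' Iteratively deform an octagon contour onto the object boundary
#'
#' Resamples the octagon to `cfg$n_contour` vertices, then repeats
#' `cfg$iterations` times: sample vertex features, run the deformation snake
#' block, add the predicted per-vertex offsets. Vertices are not re-resampled
#' between iterations; offsets accumulate on the same N vertices.
#' @param model A `snake_model`.
#' @param octagon A [contour()] from [build_octagon()].
#' @param fg A `snake_features` feature pyramid.
#' @param trace If `TRUE`, also return the contour after every iteration.
#' @return A [contour()] with `cfg$n_contour` vertices, or (with
#'   `trace = TRUE`) a list `(contour, iterations)`.
#' @export
deform_iteratively <- function(model, octagon, fg, trace = FALSE) {
  ct <- resample_contour(octagon, model$cfg$n_contour)
  iters <- vector("list", model$cfg$iterations)
  for (it in seq_len(model$cfg$iterations)) {
    vf <- vertex_features(fg, ct)
    off <- snake_block_forward(model$de_block, vf$vf)$out
    ct <- contour(unclass(ct) + off)
    iters[[it]] <- ct
  }
  if (trace) list(contour = ct, iterations = iters) else ct
}

#' Run the full contour approximation for one box
#'
#' diamond -> extreme points -> octagon -> iterative deformation.
#' @inheritParams predict_extreme_points
#' @param trace If `TRUE`, return intermediate stages.
#' @return A [contour()] (or a list of stages with `trace = TRUE`).
#' @export
snake_segment <- function(model, box, fg, trace = FALSE) {
  ex <- predict_extreme_points(model, box, fg)
  exp_ <- project_extremes(ex, box)
  oct <- build_octagon(exp_, box)
  de <- deform_iteratively(model, oct, fg, trace = trace)
  if (!trace) return(de)
  list(extremes = ex, octagon = oct, contour = de$contour,
       iterations = de$iterations)
}

# ---- loss ----------------------------------------------------------------

# Align a ground-truth contour (resampled to n vertices, clockwise) to a
# predicted contour: the GT start vertex is matched to the nearest predicted
# vertex, then correspondence follows index order cyclically.
align_gt_to_pred <- function(gt, pred) {
  n <- nrow(gt)
  d2 <- (pred[, 1] - gt[1, 1])^2 + (pred[, 2] - gt[1, 2])^2
  istar <- which.min(d2)
  tgt <- matrix(0, n, 2)
  rows <- ((istar - 1L + seq_len(n) - 1L) %% n) + 1L
  tgt[rows, ] <- gt
  tgt
}

#' Snake training loss
#'
#' Smooth-L1 (Huber, delta 1) distance between predicted and ground-truth
#' extreme points plus smooth-L1 per-vertex distance for every deformation
#' iteration. Each term is the mean of the per-coordinate Huber values over
#' its vertices; iteration terms are summed. Ground truth / prediction
#' correspondence uses nearest-start alignment then index order.
#' @param pred_extremes List `(top, leftmost, bottom, rightmost)`.
#' @param pred_contours_per_iter List of n x 2 contours, one per iteration.
#' @param gt_polygon Ground-truth polygon ([contour()], any density).
#' @return Non-negative scalar; zero iff prediction matches exactly.
#' @export
snake_training_loss <- function(pred_extremes, pred_contours_per_iter,
                                gt_polygon) {
  gt_polygon <- ensure_clockwise(gt_polygon)
  gex <- contour_extremes(gt_polygon)
  ord <- c("top", "leftmost", "bottom", "rightmost")
  pe <- do.call(rbind, lapply(pred_extremes[ord], as.numeric))
  ge <- do.call(rbind, lapply(gex[ord], as.numeric))
  loss <- mean(smooth_l1(pe, ge)$value)
  for (ct in pred_contours_per_iter) {
    ct <- as.matrix(ct)
    n <- nrow(ct)
    gt <- resample_contour(gt_polygon, n)
    tgt <- align_gt_to_pred(unclass(gt), ct)
    if (nrow(tgt) != n) stop("parameter: vertex-count mismatch")
    loss <- loss + mean(smooth_l1(ct, tgt)$value)
  }
  loss
}
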