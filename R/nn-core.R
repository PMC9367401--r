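# Minimal neural-network primitives on dense matrices.
#
# Feature maps are stored as [H*W, C] matrices in raster column-major order
# (pixel (r, c) at row r + (c-1)*H), so convolution becomes an im2col gather
# followed by one BLAS matrix multiply. All layers provide explicit forward
# and backward passes; parameters are plain numeric arrays collected in
# nested lists, updated by SGD with momentum and weight decay.

# ---- parameter initialisation -------------------------------------------

nn_init_matrix <- function(nin, nout, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / nin)  # He initialisation
  matrix(stats::rnorm(nin * nout, sd = scale), nin, nout)
}

nn_init_conv <- function(k, cin, cout) {
  list(W = nn_init_matrix(k * k * cin, cout), b = numeric(cout))
}

nn_init_dense <- function(nin, nout, scale = NULL) {
  list(W = nn_init_matrix(nin, nout, scale), b = numeric(nout))
}

# ---- SGD with momentum + weight decay (matches the detector's stated
#      optimiser: momentum 0.9, weight decay 1e-4) ------------------------

sgd_state_like <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

sgd_step <- function(params, grads, state, lr, momentum = 0.9,
                     weight_decay = 1e-4) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_v[[nm]] <- r$v
      }
      list(p = out_p, v = out_v)
    } else {
      vnew <- momentum * v - lr * (g + weight_decay * p)
      list(p = p + vnew, v = vnew)
    }
  }
  walk(params, grads, state)
}

# ---- 2-D convolution via im2col ------------------------------------------

# Precomputed gather plan for a fixed input geometry. pad with zeros; k odd.
conv_plan <- function(H, W, k, stride, pad = (k - 1L) %/% 2L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  # top-left corner (1-based, padded frame) of each output pixel's patch
  ro <- rep(seq_len(Ho), times = Wo)
  co <- rep(seq_len(Wo), each = Ho)
  r0 <- (ro - 1L) * stride
  c0 <- (co - 1L) * stride
  off <- as.matrix(expand.grid(dr = seq_len(k), dc = seq_len(k)))
  P <- Ho * Wo
  idx <- matrix(0L, P, k * k)
  for (j in seq_len(k * k)) {
    idx[, j] <- (r0 + off[j, 1]) + (c0 + off[j, 2] - 1L) * Hp
  }
  inner <- as.vector(outer(seq_len(H) + pad,
                           (seq_len(W) + pad - 1L) * Hp, `+`))
  list(H = H, W = W, k = k, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, P = P,
       idx_vec = as.vector(idx), inner = inner)
}

conv_forward <- function(X, layer, plan) {
  C <- ncol(X)
  Xp <- matrix(0, plan$Hp * plan$Wp, C)
  Xp[plan$inner, ] <- X
  patches <- Xp[plan$idx_vec, , drop = FALSE]     # (P*k2) x C
  dim(patches) <- NULL
  patches <- matrix(patches, plan$P, plan$k^2 * C)
  out <- patches %*% layer$W
  out <- sweep(out, 2, layer$b, `+`)
  list(out = out, patches = patches)
}

conv_backward <- function(dOut, layer, plan, patches, need_dx = TRUE) {
  gW <- crossprod(patches, dOut)
  gb <- colSums(dOut)
  dX <- NULL
  if (need_dx) {
    dPatch <- dOut %*% t(layer$W)                 # P x (k2*C)
    k2 <- plan$k^2
    C <- ncol(dPatch) %/% k2
    dim(dPatch) <- NULL
    dPatch <- matrix(dPatch, plan$P * k2, C)      # rows follow idx_vec order
    acc <- rowsum(dPatch, group = plan$idx_vec, reorder = FALSE)
    dXp <- matrix(0, plan$Hp * plan$Wp, C)
    dXp[as.integer(rownames(acc)), ] <- acc
    dX <- dXp[plan$inner, , drop = FALSE]
  }
  list(dX = dX, grad = list(W = gW, b = gb))
}

relu <- function(x) { x[x < 0] <- 0; x }
relu_backward <- function(dOut, act) { dOut[act <= 0] <- 0; dOut }

dense_forward <- function(X, layer) sweep(X %*% layer$W, 2, layer$b, `+`)

dense_backward <- function(dOut, X, layer, need_dx = TRUE) {
  list(dX = if (need_dx) dOut %*% t(layer$W) else NULL,
       grad = list(W = crossprod(X, dOut), b = colSums(dOut)))
}

# ---- bilinear sampling from a feature grid -------------------------------

# grid: [Hf*Wf, C] feature map at spatial stride `stride` relative to the
# image; (x, y): image coordinates. Feature cell (r, c) has its center at
# image point ((c - 0.5) * stride, (r - 0.5) * stride). Coordinates are
# clamped to the grid border (replicate padding).
bilinear_plan <- function(x, y, Hf, Wf, stride) {
  cf <- x / stride               # cell c center sits at cf = c - 0.5
  rf <- y / stride
  c0 <- floor(cf + 0.5) - 0.5    # largest center <= cf
  r0 <- floor(rf + 0.5) - 0.5
  tx <- cf - c0; ty <- rf - r0
  cl <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  ci0 <- cl(c0 + 0.5, 1, Wf); ci1 <- cl(c0 + 1.5, 1, Wf)
  ri0 <- cl(r0 + 0.5, 1, Hf); ri1 <- cl(r0 + 1.5, 1, Hf)
  i00 <- ri0 + (ci0 - 1) * Hf; i10 <- ri1 + (ci0 - 1) * Hf
  i01 <- ri0 + (ci1 - 1) * Hf; i11 <- ri1 + (ci1 - 1) * Hf
  w00 <- (1 - tx) * (1 - ty); w10 <- (1 - tx) * ty
  w01 <- tx * (1 - ty);       w11 <- tx * ty
  list(idx = cbind(i00, i10, i01, i11), w = cbind(w00, w10, w01, w11),
       Hf = Hf, Wf = Wf)
}

bilinear_sample <- function(grid, plan) {
  plan$w[, 1] * grid[plan$idx[, 1], , drop = FALSE] +
    plan$w[, 2] * grid[plan$idx[, 2], , drop = FALSE] +
    plan$w[, 3] * grid[plan$idx[, 3], , drop = FALSE] +
    plan$w[, 4] * grid[plan$idx[, 4], , drop = FALSE]
}

# Scatter-add gradients back into the grid.
bilinear_backward <- function(dOut, grid, plan) {
  C <- ncol(grid)
  all_idx <- as.vector(plan$idx)
  all_d <- rbind(plan$w[, 1] * dOut, plan$w[, 2] * dOut,
                 plan$w[, 3] * dOut, plan$w[, 4] * dOut)
  acc <- rowsum(all_d, group = all_idx, reorder = FALSE)
  dG <- matrix(0, nrow(grid), C)
  dG[as.integer(rownames(acc)), ] <- acc
  dG
}

# ---- losses --------------------------------------------------------------

# Smooth-L1 (Huber, delta = 1): 0.5 t^2 for |t| < 1 else |t| - 0.5.
smooth_l1 <- function(pred, target) {
  t <- pred - target
  a <- abs(t)
  val <- ifelse(a < 1, 0.5 * t^2, a - 0.5)
  grad <- ifelse(a < 1, t, sign(t))
  list(value = val, grad = grad)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Mean cross-entropy over rows; labels are 1-based column indices.
cross_entropy <- function(logits, labels) {
  P <- softmax_rows(logits)
  n <- nrow(logits)
  picked <- P[cbind(seq_len(n), labels)]
  dZ <- P
  dZ[cbind(seq_len(n), labels)] <- dZ[cbind(seq_len(n), labels)] - 1
  list(value = -mean(log(pmax(picked, 1e-12))), grad = dZ / n)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Mean binary cross-entropy on logits with 0/1 targets.
bce_logits <- function(logits, targets) {
  p <- sigmoid(logits)
  n <- length(logits)
  list(value = -mean(targets * log(pmax(p, 1e-12)) +
                       (1 - targets) * log(pmax(1 - p, 1e-12))),
       grad = (p - targets) / n)
}
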