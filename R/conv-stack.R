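# A plain strided convolutional stack (conv -> ReLU repeated), used both as
# the snake's image feature extractor and as the detector backbone. The
# architecture is a list of layers c(k, stride, cin, cout); im2col gather
# plans are cached per input geometry.

.plan_cache <- new.env(parent = emptyenv())

conv_stack_plans <- function(arch, H, W) {
  key <- paste(H, W, paste(unlist(arch), collapse = ","), sep = "|")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  plans <- vector("list", length(arch))
  h <- H; w <- W
  for (i in seq_along(arch)) {
    a <- arch[[i]]
    plans[[i]] <- conv_plan(h, w, a[1], a[2])
    h <- plans[[i]]$Ho; w <- plans[[i]]$Wo
  }
  out <- list(plans = plans, out_h = h, out_w = w)
  .plan_cache[[key]] <- out
  out
}

conv_stack_init <- function(arch) {
  lapply(arch, function(a) nn_init_conv(a[1], a[3], a[4]))
}

conv_stack_stride <- function(arch) prod(vapply(arch, `[`, numeric(1), 2))

# X: [H*W, cin] input. Returns final activation plus per-layer caches.
conv_stack_forward <- function(params, X, arch, H, W) {
  ps <- conv_stack_plans(arch, H, W)
  acts <- vector("list", length(arch))
  patches <- vector("list", length(arch))
  cur <- X
  for (i in seq_along(arch)) {
    cf <- conv_forward(cur, params[[i]], ps$plans[[i]])
    cur <- relu(cf$out)
    acts[[i]] <- cur
    patches[[i]] <- cf$patches
  }
  list(out = cur, acts = acts, patches = patches,
       out_h = ps$out_h, out_w = ps$out_w, plans = ps$plans)
}

# `extra`: optional list of additional gradients w.r.t. a layer's post-ReLU
# output (for taps that read intermediate feature maps).
conv_stack_backward <- function(dOut, params, cache, arch, extra = NULL) {
  grads <- vector("list", length(arch))
  d <- dOut
  for (i in rev(seq_along(arch))) {
    if (!is.null(extra) && !is.null(extra[[i]]) && i < length(arch)) {
      d <- d + extra[[i]]
    }
    d <- relu_backward(d, cache$acts[[i]])
    bw <- conv_backward(d, params[[i]], cache$plans[[i]],
                        cache$patches[[i]], need_dx = (i > 1L))
    grads[[i]] <- bw$grad
    d <- bw$dX
  }
  grads
}

# Wrap a raw [H, W, 3] image array into the flat [H*W, 3] matrix layout.
image_to_matrix <- function(img) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3] == 3L)
  matrix(img, nrow = dim(img)[1] * dim(img)[2], ncol = 3L)
}

# Feature grid container: flat [Hf*Wf, C] features + geometry.
feature_grid <- function(grid, Hf, Wf, stride) {
  structure(list(grid = grid, Hf = Hf, Wf = Wf, stride = stride),
            class = "feature_grid")
}
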