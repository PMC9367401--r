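test_that("circular_conv matches the naive cyclic-sum oracle", {
  # the hand-computed scalar example
  K <- array(c(1, 2, 3), c(3, 1, 1))
  expect_equal(as.vector(circular_conv(matrix(c(1, 0, 0, 0)), K)),
               c(2, 1, 0, 3))
  # identity kernel
  d <- 5L
  K <- array(0, c(3, d, d)); K[2, , ] <- diag(d)
  X <- matrix(rnorm(8 * d), 8, d)
  expect_equal(circular_conv(X, K), X)
  # constant rows scale by the sum of scalar taps
  Ks <- array(0, c(5, d, d))
  taps <- c(0.5, -1, 2, 0.25, 1)
  for (j in 1:5) Ks[j, , ] <- taps[j] * diag(d)
  Xc <- matrix(rep(rnorm(d), each = 9), 9, d)
  expect_equal(circular_conv(Xc, Ks), sum(taps) * Xc)
  # random instances vs the loop oracle
  set.seed(21)
  for (i in 1:50) {
    n <- sample(8:40, 1); k <- sample(c(3, 5, 7), 1)
    din <- sample(1:6, 1); dout <- sample(1:6, 1)
    X <- matrix(rnorm(n * din), n, din)
    K <- array(rnorm(k * din * dout), c(k, din, dout))
    expect_equal(circular_conv(X, K), oracle_cconv(X, K), tolerance = 1e-6)
  }
  expect_error(circular_conv(X, array(0, c(2, din, dout))), "parameter")
})

test_that("snake block is equivariant to cyclic shifts and zero at zero head", {
  set.seed(4)
  blk <- contourseg:::snake_block_init(10L, hidden = 16L)
  vf <- matrix(rnorm(32 * 10), 32, 10)
  out <- contourseg:::snake_block_forward(blk, vf)$out
  for (s in c(1, 7, 31)) {
    shift <- c((s + 1):32, 1:s)
    out_s <- contourseg:::snake_block_forward(blk, vf[shift, ])$out
    expect_equal(out_s, out[shift, ], tolerance = 1e-12)
  }
  blk0 <- blk
  blk0$head$W[] <- 0; blk0$head$b[] <- 0
  expect_true(all(contourseg:::snake_block_forward(blk0, vf)$out == 0))
})

test_that("snake block forward agrees with a layer-by-layer naive recomputation", {
  set.seed(14)
  blk <- contourseg:::snake_block_init(6L, hidden = 8L)
  vf <- matrix(rnorm(20 * 6), 20, 6)
  got <- contourseg:::snake_block_forward(blk, vf)$out
  # naive recomputation with explicit cyclic sums
  K1 <- array(blk$cc1$W, c(3, 6, 8))
  a1 <- pmax(sweep(oracle_cconv(vf, K1), 2, blk$cc1$b, `+`), 0)
  K2 <- array(blk$cc2$W, c(3, 8, 8))
  a2 <- pmax(sweep(oracle_cconv(a1, K2), 2, blk$cc2$b, `+`), 0)
  g <- apply(a2, 2, max)
  z <- cbind(a2, matrix(g, 20, 8, byrow = TRUE))
  a3 <- pmax(sweep(z %*% blk$fc1$W, 2, blk$fc1$b, `+`), 0)
  want <- sweep(a3 %*% blk$head$W, 2, blk$head$b, `+`)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("snake gradients match numerical differentiation on a tiny instance", {
  set.seed(99)
  blk <- contourseg:::snake_block_init(4L, hidden = 6L)
  vf <- matrix(rnorm(12 * 4), 12, 4)
  tgt <- matrix(rnorm(12 * 2), 12, 2)
  loss_of <- function(b) {
    out <- contourseg:::snake_block_forward(b, vf)$out
    sum(0.5 * (out - tgt)^2)
  }
  fw <- contourseg:::snake_block_forward(blk, vf)
  bw <- contourseg:::snake_block_backward(blk, fw$cache, fw$out - tgt)
  for (layer in c("cc1", "cc2", "fc1", "head")) {
    W <- blk[[layer]]$W
    for (idx in sample(length(W), 4)) {
      eps <- 1e-5
      bp <- blk; bp[[layer]]$W[idx] <- W[idx] + eps
      bm <- blk; bm[[layer]]$W[idx] <- W[idx] - eps
      num <- (loss_of(bp) - loss_of(bm)) / (2 * eps)
      expect_equal(bw$grads[[layer]]$W[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("config defaults give 40 diamond points, 128 contour points, 3 iterations", {
  cfg <- snake_config()
  expect_identical(cfg$n_diamond, 40L)
  expect_identical(cfg$n_contour, 128L)
  expect_identical(cfg$iterations, 3L)
  expect_error(snake_config(kernel_size = 4), "parameter")
  expect_error(snake_config(n_contour = 4), "parameter")
})

test_that("zero-head model is the identity pipeline on the octagon", {
  set.seed(2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  model <- snake_init(seed = 5)
  model$ex_block$head$W[] <- 0; model$ex_block$head$b[] <- 0
  model$de_block$head$W[] <- 0; model$de_block$head$b[] <- 0
  fg <- snake_features(model, img)
  b <- bbox(10, 14, 50, 46)
  # zero offsets: extremes are exactly the edge midpoints
  ex <- predict_extreme_points(model, b, fg)
  expect_equal(as.numeric(ex$top), c(30, 14))
  expect_equal(as.numeric(ex$leftmost), c(10, 30))
  expect_equal(as.numeric(ex$bottom), c(30, 46))
  expect_equal(as.numeric(ex$rightmost), c(50, 30))
  # zero offsets: deformation returns the resampled octagon unchanged
  oct <- build_octagon(ex, b)
  out <- deform_iteratively(model, oct, fg, trace = TRUE)
  expect_identical(nrow(out$contour), 128L)
  expect_length(out$iterations, 3L)
  expect_equal(unclass(out$contour),
               unclass(resample_contour(oct, 128)), tolerance = 1e-12)
  expect_error(predict_extreme_points(model, bbox(-5, 0, 10, 10), fg),
               "invalid-geometry")
})

test_that("vertex features append zero-mean relative coordinates", {
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  model <- snake_init(seed = 3)
  fg <- snake_features(model, img)
  ct <- resample_contour(box_to_diamond(bbox(8, 8, 40, 40)), 40)
  vf <- contourseg:::vertex_features(fg, ct)$vf
  expect_identical(nrow(vf), 40L)
  expect_identical(ncol(vf), snake_config()$feature_dim + 2L)
  rel <- vf[, ncol(vf) - 1:0]
  expect_lt(max(abs(colSums(rel))), 1e-6)
})

test_that("snake training loss is zero at exact match and penalizes displacement", {
  gt <- random_simple_polygon(n = 24, cx = 30, cy = 30, rmin = 10, rmax = 20)
  gt <- ensure_clockwise(gt)
  ex <- contour_extremes(gt)
  per_iter <- list(unclass(resample_contour(gt, 32)))
  expect_equal(snake_training_loss(ex, per_iter, gt), 0)
  # single vertex displaced by (1, 0): smooth-L1 of 1 is 0.5, averaged over
  # the 32 x 2 coordinates of the contour term
  ct <- per_iter[[1]]
  ct[5, 1] <- ct[5, 1] + 1
  expect_equal(snake_training_loss(ex, list(ct), gt), 0.5 / 64)
  # non-negative on random inputs
  set.seed(31)
  for (i in 1:10) {
    ctr <- ct + matrix(rnorm(64), 32, 2)
    expect_gte(snake_training_loss(ex, list(ctr), gt), 0)
  }
})

test_that("snake training is deterministic given the seed", {
  ds <- generate_dataset(n_classes = 2L, images_per_class = 4L, seed = 6)
  tc <- snake_train_config(epochs = 1L)
  m1 <- train_snake(ds, train_cfg = tc, seed = 8)
  m2 <- train_snake(ds, train_cfg = tc, seed = 8)
  expect_equal(m1$loss_curve, m2$loss_curve, tolerance = 1e-4)
  expect_equal(m1$de_block$cc1$W, m2$de_block$cc1$W, tolerance = 1e-8)
})
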