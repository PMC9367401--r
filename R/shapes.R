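#' @title Synthetic shape classes
#' @description Pseudo-animal shape classes built from truncated Fourier
#'   radial series. Each class is defined by a dominant harmonic order and an
#'   amplitude tier plus a base body color, so classes are separable both by
#'   silhouette and by appearance, while every instance varies in phase,
#'   aspect and rotation. Radial shapes (`r(theta) > 0`) are simple closed
#'   curves by construction, with exact analytic ground truth for areas and
#'   extreme points via dense sampling.
#' @name shapes
NULL

#' Default shape-class table
#'
#' Twelve classes emulating a balanced camera-trap species list: class `i`
#' combines a dominant radial harmonic of order 2-5 with one of three
#' amplitude tiers, and a distinct base hue.
#' @param n_classes Number of classes (default 12).
#' @return A list of `shape_class` lists with fields `id`, `name`, `color`
#'   (RGB in `[0,1]`), `harmonic` (dominant order), `amp_range`, `amp2`
#'   (secondary amplitude), `noise_scale`.
#' @export
default_shape_classes <- function(n_classes = 12L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("parameter: need at least 2 classes")
  tiers <- list(c(0.10, 0.16), c(0.20, 0.26), c(0.30, 0.36))
  out <- vector("list", n_classes)
  for (i in seq_len(n_classes)) {
    m <- 2L + (i - 1L) %% 4L
    tier <- tiers[[((i - 1L) %/% 4L) %% 3L + 1L]]
    hue <- (i - 1) / n_classes
    out[[i]] <- structure(list(
      id = i,
      name = sprintf("shape%02d", i),
      color = as.numeric(grDevices::col2rgb(
        grDevices::hsv(hue, 0.55, 0.70)) / 255),
      harmonic = m,
      amp_range = tier,
      amp2 = 0.05,
      noise_scale = 0.05
    ), class = "shape_class")
  }
  out
}

#' Generate one shape contour from a class
#'
#' Samples a truncated radial harmonic series
#' `r(theta) = scale * (1 + a_m cos(m theta + phi) + a_2' cos((m+1) theta + phi'))`,
#' applies a random aspect stretch and rotation, and returns a densely
#' sampled contour centered at the origin, clockwise in image coordinates.
#' Amplitudes are bounded so `r > 0`, which guarantees a simple curve; a
#' defensive simplicity check regenerates with a perturbed seed (bounded
#' retries) if ever violated.
#' @param cls A `shape_class` from [default_shape_classes()].
#' @param scale Base radius in pixels (> 0).
#' @param seed Integer seed; the same `(cls, scale, seed)` gives the same
#'   contour.
#' @param n_dense Number of dense boundary samples.
#' @return A [contour()] centered at the origin.
#' @export
make_shape <- function(cls, scale, seed, n_dense = 180L) {
  if (!is.finite(scale) || scale <= 0) stop("parameter: scale must be > 0")
  for (attempt in 0:4) {
    set.seed(as.integer(seed) + attempt * 7919L)
    amp <- stats::runif(1, cls$amp_range[1], cls$amp_range[2])
    phi <- stats::runif(1, 0, 2 * pi)
    amp2 <- stats::runif(1, 0.5, 1) * cls$amp2
    phi2 <- stats::runif(1, 0, 2 * pi)
    aspect <- stats::runif(1, 0.85, 1.2)
    rot <- stats::runif(1, 0, pi)
    th <- 2 * pi * (seq_len(n_dense) - 1) / n_dense
    r <- scale * (1 + amp * cos(cls$harmonic * th + phi) +
                    amp2 * cos((cls$harmonic + 1) * th + phi2))
    if (any(r <= 0.05 * scale)) next
    x0 <- r * cos(th) * sqrt(aspect)
    y0 <- r * sin(th) / sqrt(aspect)
    xy <- cbind(x0 * cos(rot) - y0 * sin(rot),
                x0 * sin(rot) + y0 * cos(rot))
    ct <- ensure_clockwise(contour(xy))
    if (contour_is_simple(resample_contour(ct, 48L))) return(ct)
  }
  stop("invalid-geometry: could not generate a simple shape")
}

#' Rotation-invariant radial signature of a contour
#'
#' Interpolates the centroid distance as a function of polar angle on a
#' uniform angular grid, normalizes by its mean and returns low-order
#' Fourier magnitudes (rotation invariant). Used as a sanity check that the
#' synthetic classes are separable (a nearest-centroid classifier on this
#' signature should score > 90% on clean single shapes).
#' @param xy Contour.
#' @param n_points Resampling density.
#' @param n_coef Number of Fourier magnitudes returned (orders 1..n_coef).
#' @return Numeric vector of length `n_coef`.
#' @export
radial_signature <- function(xy, n_points = 64L, n_coef = 8L) {
  ct <- resample_contour(xy, 4L * n_points)
  ctr <- colMeans(unclass(ct))
  th <- atan2(ct[, 2] - ctr[2], ct[, 1] - ctr[1])
  r <- sqrt((ct[, 1] - ctr[1])^2 + (ct[, 2] - ctr[2])^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  # periodic linear interpolation of r(theta) on a uniform angle grid
  grid <- -pi + 2 * pi * (seq_len(n_points) - 1) / n_points
  rg <- stats::approx(c(th - 2 * pi, th, th + 2 * pi), rep(r, 3),
                      xout = grid, rule = 2)$y
  rg <- rg / mean(rg)
  f <- Mod(stats::fft(rg)) / n_points
  f[2:(n_coef + 1L)]
}

#' Nearest-centroid classifier on radial signatures
#'
#' @param train_sigs Matrix of signatures (rows) for training shapes.
#' @param train_labels Class labels.
#' @param test_sigs Matrix of signatures to classify.
#' @return Predicted labels.
#' @export
classify_by_signature <- function(train_sigs, train_labels, test_sigs) {
  labs <- sort(unique(train_labels))
  cents <- t(vapply(labs, function(l) {
    colMeans(train_sigs[train_labels == l, , drop = FALSE])
  }, numeric(ncol(train_sigs))))
  d <- outer(seq_len(nrow(test_sigs)), seq_along(labs),
             Vectorize(function(i, j) sum((test_sigs[i, ] - cents[j, ])^2)))
  labs[max.col(-d)]
}
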