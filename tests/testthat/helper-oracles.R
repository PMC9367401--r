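# Independent brute-force oracles used across the suite. These deliberately
# use naive algorithms (dense walks, per-pixel ray casting, explicit loops)
# so they share no code with the implementation they check.

# Uniform resampling oracle: walk the closed boundary at `steps` dense
# points and pick every (steps/n)-th.
oracle_resample <- function(xy, n, steps = 1e5) {
  closed <- rbind(xy, xy[1, , drop = FALSE])
  seg <- diff(closed)
  seglen <- sqrt(rowSums(seg^2))
  L <- sum(seglen)
  cum <- c(0, cumsum(seglen))
  out <- matrix(0, n, 2)
  for (j in seq_len(n)) {
    target <- (j - 1) * L / n
    i <- max(which(cum <= target + 1e-12))
    i <- min(i, nrow(xy))
    t <- if (seglen[i] > 0) (target - cum[i]) / seglen[i] else 0
    out[j, ] <- closed[i, ] + t * seg[i, ]
  }
  out
}

# Per-pixel ray-casting point-in-polygon oracle (even-odd rule).
oracle_mask <- function(xy, height, width) {
  n <- nrow(xy)
  m <- matrix(FALSE, height, width)
  for (r in seq_len(height)) {
    py <- r - 0.5
    for (c in seq_len(width)) {
      px <- c - 0.5
      inside <- FALSE
      for (i in seq_len(n)) {
        j <- if (i == n) 1L else i + 1L
        yi <- xy[i, 2]; yj <- xy[j, 2]
        if ((yi <= py) != (yj <= py)) {
          xint <- xy[i, 1] + (py - yi) * (xy[j, 1] - xy[i, 1]) / (yj - yi)
          if (px < xint) inside <- !inside
        }
      }
      m[r, c] <- inside
    }
  }
  m
}

# Naive cyclic correlation oracle for circular convolution.
oracle_cconv <- function(features, kernel) {
  n <- nrow(features); k <- dim(kernel)[1]; dp <- dim(kernel)[3]
  half <- (k - 1) %/% 2
  out <- matrix(0, n, dp)
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      src <- ((i - 1 + (j - 1) - half) %% n) + 1
      out[i, ] <- out[i, ] + features[src, ] %*% kernel[j, , ]
    }
  }
  out
}

# Random simple star-shaped polygon (radial, so guaranteed simple).
random_simple_polygon <- function(n = 12, cx = 32, cy = 32, rmin = 5,
                                  rmax = 25) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  contour(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# Brute-force greedy matcher + exact staircase AP for tiny instances.
oracle_ap <- function(scores, tp, n_gt) {
  ord <- order(-scores)
  tp <- tp[ord]
  best <- 0
  ps <- numeric(0); rs <- numeric(0)
  for (i in seq_along(tp)) {
    ps <- c(ps, sum(tp[1:i]) / i)
    rs <- c(rs, sum(tp[1:i]) / n_gt)
  }
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(r) {
    ok <- rs >= r - 1e-12
    if (!any(ok)) 0 else max(ps[ok])
  }, numeric(1))
  mean(vals)
}

# Tiny in-memory dataset shared by the slower training tests (built once).
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(n_classes = 4L, images_per_class = 6L,
                                 seed = 42L)
    }
    cache
  }
})
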