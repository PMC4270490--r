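# Independent oracles and small fixture builders used across the suite.
# Oracles are written as plain double loops / first-principles formulas so
# they share no code path with the implementation they check.

# Exhaustive pairwise point-set distance (um) between two point matrices.
oracle_pointset_distance <- function(pts_a, pts_b, um_per_pixel) {
  best <- Inf
  for (i in seq_len(nrow(pts_a))) {
    for (j in seq_len(nrow(pts_b))) {
      d <- sqrt((pts_a[i, 1] - pts_b[j, 1])^2 + (pts_a[i, 2] - pts_b[j, 2])^2)
      if (d < best) best <- d
    }
  }
  best * um_per_pixel
}

# O(n^2) nearest-neighbor distances between centroid rows (um).
oracle_nn_distances <- function(ctr, um_per_pixel) {
  n <- nrow(ctr)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((ctr[i, ] - ctr[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best * um_per_pixel
  }
  out
}

# Longest uncovered sub-interval of [0, L] given covered intervals
# (loop-based sweep, independent of the package's merge).
oracle_longest_gap <- function(intervals, L) {
  ord <- order(intervals[, 1])
  intervals <- intervals[ord, , drop = FALSE]
  gap <- intervals[1, 1]
  hi <- intervals[1, 2]
  i <- 2
  while (i <= nrow(intervals)) {
    if (intervals[i, 1] > hi) gap <- max(gap, intervals[i, 1] - hi)
    if (intervals[i, 2] > hi) hi <- intervals[i, 2]
    i <- i + 1
  }
  max(gap, L - hi)
}

# Principal-axis extent of mask pixel coordinates via prcomp (PCA oracle).
oracle_pca_length_um <- function(mask, um_per_pixel) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  pc <- stats::prcomp(pts)
  s <- pc$x[, 1]
  (max(s) - min(s) + 1) * um_per_pixel
}

# Aspect ratio from second moments of points densely sampled inside the
# polygon (covariance-eigenvalue oracle).
oracle_polygon_aspect <- function(outline, n_grid = 400) {
  xr <- range(outline[, 1]); yr <- range(outline[, 2])
  gx <- seq(xr[1], xr[2], length.out = n_grid)
  gy <- seq(yr[1], yr[2], length.out = n_grid)
  g <- expand.grid(x = gx, y = gy)
  inside <- sp_point_in_polygon(g$x, g$y, outline[, 1], outline[, 2])
  pts <- g[inside, ]
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$values
  sqrt(ev[1] / ev[2])
}

# Even-odd ray-casting point-in-polygon (vectorized over points).
sp_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    slope <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < slope))
    j <- i
  }
  inside
}

# Permutation two-sample test (difference of means) p-value.
oracle_permutation_p <- function(a, b, n_perm = 1e4, seed = 99) {
  withr::with_seed(seed, {
    obs <- abs(mean(a) - mean(b))
    pool <- c(a, b)
    na <- length(a)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(length(pool), na)
      if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
}

# Noiseless variant of a preset.
noiseless <- function(preset) {
  preset$noise$gaussian_sd <- 0
  preset$noise$poisson_like <- FALSE
  preset
}

# A small rendered fixture shared by IO/profile tests.
fixture_fiber <- function(preset = NULL, seed = 1, um_per_pixel = 0.1,
                          noise = FALSE, orientation_deg = 0) {
  presets <- default_genotype_presets()
  preset <- preset %||% presets$control
  if (!noise) preset <- noiseless(preset)
  simulate_fiber(preset, length_um = 40, width_um = 6,
                 um_per_pixel = um_per_pixel,
                 orientation_deg = orientation_deg, seed = seed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
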