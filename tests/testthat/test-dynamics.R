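circle_poly <- function(r = 10, n = 128, ctr = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

ellipse_poly <- function(a, b, ang = 0, n = 256, ctr = c(0, 0)) {
  u <- c(cos(ang), sin(ang))
  myoquant:::ellipse_polygon(ctr, a, b, u, n = n)
}

test_that("aspect ratio matches closed forms and the sampled-moment oracle", {
  expect_equal(aspect_ratio(circle_poly()), 1, tolerance = 1e-6)
  expect_equal(aspect_ratio(ellipse_poly(30, 10, ang = 0.7)), 3,
               tolerance = 0.05 / 3)
  withr::with_seed(5, {
    for (i in 1:5) {
      a <- runif(1, 12, 40); b <- runif(1, 8, a)
      poly <- ellipse_poly(a, b, ang = runif(1, 0, pi), n = 90)
      expect_equal(aspect_ratio(poly), oracle_polygon_aspect(poly),
                   tolerance = 0.02)
    }
  })
  expect_error(aspect_ratio(cbind(c(0, 1), c(0, 1))), "degenerate")
  expect_error(aspect_ratio(cbind(c(0, 1, 2), c(0, 0, 0))), "degenerate")
})

test_that("aspect ratio is invariant under similarity transforms", {
  poly <- ellipse_poly(25, 11, ang = 0.3)
  base <- aspect_ratio(poly)
  for (i in 1:5) {
    ang <- i; scale <- 0.5 * i; shift <- c(13 * i, -7 * i)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    moved <- sweep(scale * poly %*% R, 2, shift, `+`)
    expect_equal(aspect_ratio(moved), base, tolerance = 1e-9)
  }
})

test_that("aspect extremes report the two simulated shape states", {
  trks <- simulate_nucleus_tracks(10, 60, 30,
                                  dynamics = list(shape_change_rate_per_hr = 4,
                                                  direction_flip_rate_per_hr = 0,
                                                  ar_elongated = 1.8,
                                                  ar_spherical = 1.1,
                                                  ar_jitter_sd = 0),
                                  seed = 8)
  switched <- Filter(function(t) attr(t, "true_shape_events") > 0, trks)
  expect_gt(length(switched), 0)
  for (t in switched) {
    ex <- aspect_extremes(t)
    expect_equal(ex[["ar_max"]], 1.8, tolerance = 0.01)
    expect_equal(ex[["ar_min"]], 1.1, tolerance = 0.01)
  }
  one_frame <- nucleus_track(data.frame(t_s = 0, x_px = 0, y_px = 0),
                             list(circle_poly()), 1)
  expect_error(aspect_extremes(one_frame), "5 frames")
})

test_that("shape-change counting is a hysteresis state machine", {
  mk_track <- function(ars, dt_s = 60) {
    n <- length(ars)
    nucleus_track(data.frame(t_s = seq(0, by = dt_s, length.out = n),
                             x_px = 0, y_px = seq_len(n)),
                  lapply(ars, function(a) ellipse_poly(10 * a, 10)), 0.2)
  }
  ramp <- mk_track(seq(1, 2, length.out = 30), dt_s = 60)
  expect_equal(attr(count_shape_changes(ramp), "events"), 1L)
  flat <- mk_track(rep(1, 30))
  expect_equal(as.numeric(count_shape_changes(flat)), 0)
  expect_error(count_shape_changes(ramp, enter_elongated = 1.1,
                                   exit_elongated = 1.3), "exceed")
  # oversampling invariance: duplicating frames adds no events
  ars <- c(rep(1.1, 10), rep(1.8, 10), rep(1.1, 10))
  base <- mk_track(ars, dt_s = 120)
  dup <- mk_track(rep(ars, each = 2), dt_s = 60)
  expect_equal(attr(count_shape_changes(base), "events"),
               attr(count_shape_changes(dup), "events"))
})

test_that("simulated switching rates are recovered unbiasedly on a rate grid", {
  for (rate in c(2, 4)) {
    trks <- simulate_nucleus_tracks(60, 60, 30,
                                    dynamics = list(shape_change_rate_per_hr = rate,
                                                    direction_flip_rate_per_hr = 0),
                                    seed = 40 + rate)
    rates <- vapply(trks, function(t) as.numeric(count_shape_changes(t)),
                    numeric(1))
    expect_equal(mean(rates), rate, tolerance = 3 * sqrt(rate / 60) / rate)
  }
})

test_that("direction-change fraction handles monotone, reversing and noisy cohorts", {
  mono <- simulate_nucleus_tracks(10, 60, 30,
                                  dynamics = list(direction_flip_rate_per_hr = 0,
                                                  shape_change_rate_per_hr = 0),
                                  seed = 3)
  expect_equal(direction_change_fraction(mono), 0)
  # every track reverses exactly once at mid-time -> 100%
  n <- 121
  y <- c(seq(0, 30, length.out = 61), seq(29.5, 0, length.out = 60))
  one_rev <- nucleus_track(data.frame(t_s = seq(0, 3600, length.out = n),
                                      x_px = 0, y_px = y / 0.2), NULL, 0.2)
  expect_equal(direction_change_fraction(list(one_rev, one_rev)), 100)
  still <- nucleus_track(data.frame(t_s = seq(0, 3600, length.out = n),
                                    x_px = 0, y_px = rep(0, n)), NULL, 0.2)
  expect_warning(pct <- direction_change_fraction(list(still)), "stationary")
  expect_equal(pct, 0)
})

test_that("kymographs show a constant band for static disks and the right slope when moving", {
  render_disk <- function(cx, cy, r = 4, ny = 40, nx = 40) {
    m <- matrix(0, ny, nx)
    for (row in 1:ny) for (col in 1:nx)
      if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) m[row, col] <- 100
    m
  }
  n <- 12
  tr_still <- nucleus_track(data.frame(t_s = seq(0, by = 60, length.out = n),
                                       x_px = 20, y_px = 20), NULL, 0.2)
  movie_still <- lapply(1:n, function(i) render_disk(20, 20))
  k <- build_kymograph(tr_still, movie_still)
  expect_true(all(apply(k, 2, function(col) max(col) - min(col) == 0)))
  # constant velocity: centroid column drifts linearly at v px/frame
  v <- 1.5
  ys <- 8 + v * (0:(n - 1))
  tr_mov <- nucleus_track(data.frame(t_s = seq(0, by = 60, length.out = n),
                                     x_px = 20, y_px = ys), NULL, 0.2)
  movie_mov <- lapply(seq_len(n), function(i) render_disk(20, ys[i]))
  km <- build_kymograph(tr_mov, movie_mov)
  centers <- apply(km, 1, function(row) weighted.mean(seq_along(row), row))
  fit <- stats::lm(centers ~ seq_len(n))
  expect_equal(unname(stats::coef(fit)[2]), v, tolerance = 0.05)
  expect_error(build_kymograph(tr_mov, list()), "empty movie")
})
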