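#' Nucleus track
#'
#' Time series of one nucleus's centroid and outline. `frames` is a
#' data.frame with `t_s`, `x_px`, `y_px`; `outlines` is a list of polygon
#' matrices (pixel coordinates) parallel to the rows of `frames`.
#'
#' @param frames data.frame with strictly increasing `t_s` plus `x_px`, `y_px`.
#' @param outlines list of outline polygons, one per frame (optional).
#' @param um_per_pixel pixel size in micrometres.
#' @return An object of class `nucleus_track`.
#' @export
nucleus_track <- function(frames, outlines = NULL, um_per_pixel = 1) {
  stopifnot(is.data.frame(frames),
            all(c("t_s", "x_px", "y_px") %in% names(frames)))
  if (is.unsorted(frames$t_s, strictly = TRUE))
    stop("frame timestamps must be strictly increasing", call. = FALSE)
  if (!is.null(outlines) && length(outlines) != nrow(frames))
    stop("one outline per frame required", call. = FALSE)
  structure(list(frames = frames, outlines = outlines,
                 um_per_pixel = um_per_pixel,
                 duration_min = (max(frames$t_s) - min(frames$t_s)) / 60),
            class = "nucleus_track")
}

# Piecewise-constant state sampler for a Poisson switching process:
# event times on [0, T_hr], state flips at each event.
poisson_switch_states <- function(rate_per_hr, t_hr, init_state) {
  if (rate_per_hr <= 0) return(rep(init_state, length(t_hr)))
  T_hr <- max(t_hr)
  n_ev <- stats::rpois(1, rate_per_hr * T_hr)
  ev <- sort(stats::runif(n_ev, 0, T_hr))
  n_before <- findInterval(t_hr, ev)
  ifelse(n_before %% 2 == 0, init_state, 3L - init_state)
}

#' Simulate translocating nucleus tracks
#'
#' Each track alternates between a spherical and an elongated shape state as
#' a Poisson process, and its centroid advances along the movement axis at a
#' constant speed whose sign flips as an independent Poisson process.
#' Outlines are ellipses (constant area) realizing the current aspect ratio,
#' major axis along the movement axis; a small multiplicative jitter on the
#' aspect ratio emulates outline measurement noise.
#'
#' @param n_nuclei number of tracks.
#' @param duration_min track duration (>= 20 min, matching the time-lapse
#'   protocol the dynamics statistics assume).
#' @param frame_interval_s sampling interval in seconds; must be well below
#'   the expected dwell time of the fastest Poisson process.
#' @param dynamics list with `speed_um_min`, `shape_change_rate_per_hr`,
#'   `direction_flip_rate_per_hr`, `ar_elongated`, `ar_spherical`,
#'   optional `ar_jitter_sd` (multiplicative, default 0.02) and
#'   `radius_um` (equivalent circular radius, default 1.2).
#' @param seed integer seed.
#' @param um_per_pixel pixel size of the track coordinates.
#' @return List of [nucleus_track()] objects. Each track carries its true
#'   event counts as attributes `true_shape_events` and `true_flips`.
#' @export
simulate_nucleus_tracks <- function(n_nuclei, duration_min, frame_interval_s,
                                    dynamics, seed = NULL, um_per_pixel = 0.2) {
  if (duration_min < 20)
    stop("duration_min must be >= 20 for rate estimates", call. = FALSE)
  dyn <- utils::modifyList(list(speed_um_min = 0.3,
                                shape_change_rate_per_hr = 4,
                                direction_flip_rate_per_hr = 0.2,
                                ar_elongated = 1.8, ar_spherical = 1.1,
                                ar_jitter_sd = 0.02, radius_um = 1.2),
                           dynamics)
  max_rate <- max(dyn$shape_change_rate_per_hr, dyn$direction_flip_rate_per_hr)
  if (max_rate > 0 && frame_interval_s >= 3600 / max_rate)
    stop("undersampling: frame_interval_s is not below the expected dwell ",
         "time of the fastest switching process", call. = FALSE)
  with_seed_if(seed, {
    t_s <- seq(0, duration_min * 60, by = frame_interval_s)
    t_hr <- t_s / 3600
    area <- pi * dyn$radius_um^2
    lapply(seq_len(n_nuclei), function(i) {
      shape_state <- poisson_switch_states(dyn$shape_change_rate_per_hr, t_hr, 1L)
      dir_state <- poisson_switch_states(dyn$direction_flip_rate_per_hr, t_hr,
                                         sample(1:2, 1))
      sgn <- ifelse(dir_state == 1L, 1, -1)
      dt_min <- c(0, diff(t_s)) / 60
      y_um <- cumsum(sgn * dyn$speed_um_min * dt_min)
      x_um <- rep(5, length(t_s))
      ar <- ifelse(shape_state == 1L, dyn$ar_spherical, dyn$ar_elongated)
      if (dyn$ar_jitter_sd > 0)
        ar <- pmax(1, ar * exp(stats::rnorm(length(ar), 0, dyn$ar_jitter_sd)))
      outlines <- lapply(seq_along(t_s), function(j) {
        b <- sqrt(area / (pi * ar[j]))
        a <- ar[j] * b
        ellipse_polygon(c(x_um[j], y_um[j] + 20) / um_per_pixel,
                        a / um_per_pixel, b / um_per_pixel, c(0, 1))
      })
      tr <- nucleus_track(data.frame(t_s = t_s,
                                     x_px = x_um / um_per_pixel,
                                     y_px = (y_um + 20) / um_per_pixel),
                          outlines, um_per_pixel)
      attr(tr, "true_shape_events") <- sum(diff(shape_state) != 0)
      attr(tr, "true_flips") <- sum(diff(dir_state) != 0)
      tr
    })
  })
}

#' Centroid track (crawling larva)
#'
#' @param samples data.frame with `t_s`, `x_um`, `y_um` (timestamps
#'   increasing).
#' @param stimulus_point optional 2-vector, location of the attractant.
#' @return Object of class `centroid_track`.
#' @export
centroid_track <- function(samples, stimulus_point = NULL) {
  stopifnot(is.data.frame(samples),
            all(c("t_s", "x_um", "y_um") %in% names(samples)))
  if (is.unsorted(samples$t_s, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  structure(list(samples = samples, stimulus_point = stimulus_point),
            class = "centroid_track")
}

#' Simulate a larval crawling track
#'
#' Correlated random walk toward a fixed stimulus point: each step has
#' constant length `mean_speed_um_s * frame_interval_s`, and the heading
#' relaxes toward the bearing to the stimulus while accumulating Gaussian
#' noise. With `heading_noise = 0` the path is a straight line toward the
#' stimulus.
#'
#' @param mean_speed_um_s crawl speed (>= 0).
#' @param heading_noise heading diffusion (rad per sqrt(s)).
#' @param duration_s track duration.
#' @param frame_interval_s sampling interval.
#' @param seed integer seed.
#' @param turn_rate relaxation rate of the heading toward the stimulus (1/s).
#' @return A [centroid_track()] with attribute `true_path_length_um`.
#' @export
simulate_larval_track <- function(mean_speed_um_s, heading_noise = 0.2,
                                  duration_s = 60, frame_interval_s = 1,
                                  seed = NULL, turn_rate = 0.5) {
  if (mean_speed_um_s < 0) stop("mean_speed_um_s must be >= 0", call. = FALSE)
  with_seed_if(seed, {
    t_s <- seq(0, duration_s, by = frame_interval_s)
    n <- length(t_s)
    stim <- c(2 * mean_speed_um_s * duration_s + 1000, 0)
    x <- numeric(n); y <- numeric(n)
    theta <- 0   # initial heading = bearing to the stimulus
    dt <- frame_interval_s
    for (i in 2:n) {
      bearing <- atan2(stim[2] - y[i - 1], stim[1] - x[i - 1])
      d <- ((bearing - theta + pi) %% (2 * pi)) - pi
      theta <- theta + turn_rate * d * dt +
        heading_noise * sqrt(dt) * stats::rnorm(1)
      step <- mean_speed_um_s * dt
      x[i] <- x[i - 1] + step * cos(theta)
      y[i] <- y[i - 1] + step * sin(theta)
    }
    tr <- centroid_track(data.frame(t_s = t_s, x_um = x, y_um = y),
                         stimulus_point = stim)
    attr(tr, "true_path_length_um") <- mean_speed_um_s * (duration_s)
    tr
  })
}
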