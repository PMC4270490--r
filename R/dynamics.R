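#' Aspect ratio of a nucleus outline
#'
#' Major/minor axis ratio of the outline's inertia-equivalent ellipse,
#' computed from the exact second-order area moments of the polygon
#' (Green's-theorem formulas), so the result is invariant to rotation,
#' translation, uniform scaling, and vertex order.
#'
#' @param outline polygon matrix with columns x, y (any consistent unit).
#' @return Ratio >= 1.
#' @export
aspect_ratio <- function(outline) {
  x <- outline[, 1]; y <- outline[, 2]
  n <- length(x)
  if (n < 3) stop("degenerate polygon: fewer than 3 vertices", call. = FALSE)
  xp <- c(x[-1], x[1]); yp <- c(y[-1], y[1])
  cr <- x * yp - xp * y
  A <- sum(cr) / 2
  if (abs(A) < .Machine$double.eps * 100)
    stop("degenerate polygon: zero area", call. = FALSE)
  cx <- sum((x + xp) * cr) / (6 * A)
  cy <- sum((y + yp) * cr) / (6 * A)
  ixx <- sum((y^2 + y * yp + yp^2) * cr) / 12
  iyy <- sum((x^2 + x * xp + xp^2) * cr) / 12
  ixy <- sum((x * yp + 2 * x * y + 2 * xp * yp + xp * y) * cr) / 24
  # central covariance of the region
  cxx <- iyy / A - cx^2
  cyy <- ixx / A - cy^2
  cxy <- ixy / A - cx * cy
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  if (ev[2] <= 0) stop("degenerate polygon: zero minor axis", call. = FALSE)
  sqrt(ev[1] / ev[2])
}

track_aspect_ratios <- function(track) {
  if (is.null(track$outlines))
    stop("track carries no outlines; aspect ratios unavailable", call. = FALSE)
  vapply(track$outlines, aspect_ratio, numeric(1))
}

#' Aspect-ratio extremes of a track
#'
#' @param track a [nucleus_track()] with outlines (>= 5 frames).
#' @return Named vector `c(ar_max, ar_min)`.
#' @export
aspect_extremes <- function(track) {
  if (nrow(track$frames) < 5)
    stop("need at least 5 frames for aspect-ratio extremes", call. = FALSE)
  ar <- track_aspect_ratios(track)
  c(ar_max = max(ar), ar_min = min(ar))
}

#' Count nuclear shape changes per hour
#'
#' Two-state classifier with hysteresis: a nucleus becomes "elongated" when
#' its aspect ratio crosses `enter_elongated` upward and "spherical" when
#' it crosses `exit_elongated` downward; each state transition is one shape
#' change. Hysteresis makes the count invariant to temporal oversampling
#' and robust to outline noise. The rate is events divided by track
#' duration in hours.
#'
#' @param track a [nucleus_track()] of at least 20 min.
#' @param enter_elongated upper threshold (default 1.4).
#' @param exit_elongated lower threshold (default 1.2); must be below
#'   `enter_elongated`.
#' @return Events per hour (attribute `events` carries the raw count).
#' @export
count_shape_changes <- function(track, enter_elongated = 1.4,
                                exit_elongated = 1.2) {
  if (enter_elongated <= exit_elongated)
    stop("enter_elongated must exceed exit_elongated", call. = FALSE)
  if (track$duration_min < 20)
    stop("need >= 20 min of tracking for a rate estimate", call. = FALSE)
  ar <- track_aspect_ratios(track)
  state <- NA_integer_   # 1 spherical, 2 elongated
  events <- 0L
  for (v in ar) {
    if (is.na(state)) {
      if (v >= enter_elongated) state <- 2L
      else if (v <= exit_elongated) state <- 1L
      # between thresholds before first classification: remain undecided
    } else if (state == 1L && v >= enter_elongated) {
      state <- 2L; events <- events + 1L
    } else if (state == 2L && v <= exit_elongated) {
      state <- 1L; events <- events + 1L
    }
  }
  rate <- events / (track$duration_min / 60)
  attr(rate, "events") <- events
  rate
}

#' Fraction of nuclei that change direction, per hour
#'
#' For each track, axial displacement is evaluated over a sliding window;
#' windows whose net displacement exceeds `min_disp_um` define a motion
#' sign. A track "changed direction" if the motion sign flips at least
#' once. The reported percentage is the mean of per-track indicators, each
#' divided by the track duration in hours (so a reversal seen in a 30-min
#' track counts double), times 100.
#'
#' @param tracks list of [nucleus_track()] objects (>= 20 min each).
#' @param window_frames sliding-window length in frames.
#' @param min_disp_um minimum net displacement that counts as motion; the
#'   threshold below which movement is treated as jitter is a free
#'   parameter (default 0.5).
#' @param axis unit 2-vector of the movement axis (default: the fiber long
#'   axis is vertical in simulated tracks).
#' @return Percentage in \[0, 100\] (per hour).
#' @export
direction_change_fraction <- function(tracks, window_frames = 5,
                                      min_disp_um = 0.5, axis = c(0, 1)) {
  stopifnot(length(tracks) >= 1)
  axis <- axis / sqrt(sum(axis^2))
  any_motion <- FALSE
  contrib <- vapply(tracks, function(tr) {
    if (tr$duration_min < 20)
      stop("all tracks must be >= 20 min", call. = FALSE)
    a <- (tr$frames$x_px * axis[1] + tr$frames$y_px * axis[2]) * tr$um_per_pixel
    n <- length(a)
    w <- min(window_frames, n - 1)
    disp <- a[(1 + w):n] - a[1:(n - w)]
    signs <- sign(disp[abs(disp) >= min_disp_um])
    if (length(signs)) any_motion <<- TRUE
    changed <- length(signs) >= 2 && any(diff(signs) != 0)
    as.numeric(changed) / (tr$duration_min / 60)
  }, numeric(1))
  if (!any_motion)
    warning("no track exceeded the minimum displacement: all stationary",
            call. = FALSE)
  100 * mean(contrib)
}

#' Build a kymograph from a track and movie
#'
#' Extracts, for every frame, the intensity strip along the track's net
#' movement axis (a fixed line through the mean centroid), averaging across
#' `strip_width_px` perpendicular to it, and stacks the strips as rows
#' ordered by time. The position axis is flipped when needed so net motion
#' runs toward increasing position ("upward" when the montage is viewed
#' with the position axis vertical). Samples falling outside a frame are
#' padded with zeros and flagged.
#'
#' @param track a [nucleus_track()].
#' @param movie list of intensity matrices, one per track frame.
#' @param strip_width_px averaging width perpendicular to the axis.
#' @param pad_px extra strip length beyond the centroid excursion.
#' @return Matrix (rows = time, columns = position along the axis) with
#'   attributes `axis`, `flipped`, `padded`, `positions_px`.
#' @export
build_kymograph <- function(track, movie, strip_width_px = 5, pad_px = 10) {
  if (length(movie) == 0) stop("empty movie", call. = FALSE)
  if (length(movie) != nrow(track$frames))
    stop("movie frames must align with track frames", call. = FALSE)
  ctr <- cbind(track$frames$x_px, track$frames$y_px)
  net <- ctr[nrow(ctr), ] - ctr[1, ]
  if (sqrt(sum(net^2)) < .Machine$double.eps) net <- c(0, 1)
  u <- net / sqrt(sum(net^2))
  v <- c(-u[2], u[1])
  base <- colMeans(ctr)
  s_ctr <- (ctr[, 1] - base[1]) * u[1] + (ctr[, 2] - base[2]) * u[2]
  s_grid <- seq(floor(min(s_ctr)) - pad_px, ceiling(max(s_ctr)) + pad_px, by = 1)
  half <- (strip_width_px - 1) / 2
  lanes <- if (strip_width_px > 1) seq(-half, half, by = 1) else 0
  padded <- FALSE
  rows <- lapply(seq_along(movie), function(i) {
    fr <- movie[[i]]
    vals <- vapply(s_grid, function(s) {
      px <- base[1] + s * u[1] + lanes * v[1]
      py <- base[2] + s * u[2] + lanes * v[2]
      out <- px < 0 | px > ncol(fr) - 1 | py < 0 | py > nrow(fr) - 1
      if (any(out)) padded <<- TRUE
      mean(sample_bilinear(fr, px, py, outside = 0))
    }, numeric(1))
    vals
  })
  k <- do.call(rbind, rows)
  flipped <- FALSE
  if (s_ctr[length(s_ctr)] < s_ctr[1]) {   # net motion toward smaller s
    k <- k[, rev(seq_len(ncol(k))), drop = FALSE]
    s_grid <- rev(-s_grid)
    flipped <- TRUE
  }
  attr(k, "axis") <- u
  attr(k, "flipped") <- flipped
  attr(k, "padded") <- padded
  attr(k, "positions_px") <- s_grid
  k
}

#' Cohort dynamics report
#'
#' Per-track aspect extremes, shape-change rates, and direction-change
#' indicators, plus cohort summaries.
#'
#' @param tracks list of [nucleus_track()] objects.
#' @param ... passed to [count_shape_changes()] and
#'   [direction_change_fraction()].
#' @return List with `per_track` (data.frame) and `cohort` (named list).
#' @export
dynamics_report <- function(tracks, ...) {
  per <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    ex <- aspect_extremes(tracks[[i]])
    data.frame(track_id = i, ar_max = ex[["ar_max"]], ar_min = ex[["ar_min"]],
               shape_changes_per_hr = as.numeric(count_shape_changes(tracks[[i]])))
  }))
  pct <- direction_change_fraction(tracks, ...)
  list(per_track = per,
       cohort = list(ar_max_mean = mean(per$ar_max), ar_max_sd = stats::sd(per$ar_max),
                     ar_min_mean = mean(per$ar_min), ar_min_sd = stats::sd(per$ar_min),
                     shape_rate_mean = mean(per$shape_changes_per_hr),
                     shape_rate_sd = stats::sd(per$shape_changes_per_hr),
                     pct_direction_changers_per_hr = pct))
}
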