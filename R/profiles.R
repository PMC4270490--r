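#' Select the end-to-nucleus profile ROI
#'
#' Builds an oriented rectangular box aligned to the shortest segment
#' between the given end contour and the nearest nucleus outline. The same
#' ROI (a pixel-coordinate construct, not channel data) is reused for every
#' channel, so ratios always compare identical pixel sets. If the box at
#' the requested width leaves the fiber mask, the width is shrunk in 1-px
#' steps with a warning; below `min_width_um` an error is raised.
#'
#' @param fiber a [fiber_geometry()].
#' @param nuclei a [nucleus_set()].
#' @param end `"dorsal"` or `"ventral"`.
#' @param width_um box width (short axis); the published protocol fixes it
#'   per experiment but never states the value, so it is a parameter
#'   (default 2).
#' @param min_width_um smallest admissible width after shrinking.
#' @return Object of class `profile_roi`: `origin` (end-contour point, px),
#'   `dir` (unit vector toward the nucleus), `length_px`, `width_px`,
#'   `end`, `nucleus_id`, `um_per_pixel`.
#' @export
select_profile_roi <- function(fiber, nuclei, end = c("dorsal", "ventral"),
                               width_um = 2, min_width_um = 0.6) {
  end <- match.arg(end)
  if (length(nuclei) < 1) stop("no nuclei to anchor the ROI", call. = FALSE)
  contour <- fiber$end_contours[[end]]
  best <- Inf; p_end <- NULL; p_nuc <- NULL; best_id <- NA_integer_
  for (n in nuclei$nuclei) {
    d2 <- outer(contour[, 1], n$outline[, 1], `-`)^2 +
      outer(contour[, 2], n$outline[, 2], `-`)^2
    ij <- arrayInd(which.min(d2), dim(d2))
    if (d2[ij] < best) {
      best <- d2[ij]
      p_end <- contour[ij[1], ]
      p_nuc <- n$outline[ij[2], ]
      best_id <- n$id
    }
  }
  len_px <- sqrt(best)
  if (len_px < 3)
    stop("end-to-nucleus span too short for a profile", call. = FALSE)
  dir <- (p_nuc - p_end) / len_px
  width_px <- max(1, round(width_um / fiber$um_per_pixel))
  while (width_px >= max(1, round(min_width_um / fiber$um_per_pixel))) {
    roi <- structure(list(origin = as.numeric(p_end), dir = as.numeric(dir),
                          length_px = len_px, width_px = width_px,
                          end = end, nucleus_id = best_id,
                          um_per_pixel = fiber$um_per_pixel),
                     class = "profile_roi")
    pts <- roi_sample_points(roi)
    inside <- fiber$mask[cbind(pmin(pmax(round(pts[, 2]), 0), nrow(fiber$mask) - 1) + 1,
                               pmin(pmax(round(pts[, 1]), 0), ncol(fiber$mask) - 1) + 1)]
    if (all(inside)) {
      if (width_px < max(1, round(width_um / fiber$um_per_pixel)))
        warning(sprintf("profile box narrowed to %.2f um to stay inside the fiber",
                        width_px * fiber$um_per_pixel), call. = FALSE)
      return(roi)
    }
    width_px <- width_px - 1
  }
  stop("profile box cannot fit inside the fiber at the minimum width",
       call. = FALSE)
}

# Sample grid of a profile ROI: one row per sample point, columns x, y,
# step (longitudinal index) and lane (lateral index).
roi_sample_points <- function(roi) {
  steps <- unique(c(0:floor(roi$length_px), roi$length_px))
  half <- (roi$width_px - 1) / 2
  lanes <- if (roi$width_px > 1) seq(-half, half, by = 1) else 0
  v <- c(-roi$dir[2], roi$dir[1])
  g <- expand.grid(step = steps, lane = lanes)
  cbind(x = roi$origin[1] + g$step * roi$dir[1] + g$lane * v[1],
        y = roi$origin[2] + g$step * roi$dir[2] + g$lane * v[2],
        step = g$step, lane = g$lane)
}

#' Compute a raw ratio profile along an ROI
#'
#' At each 1-px longitudinal step, intensities are averaged across the box
#' width (arithmetic mean, bilinear sampling restricted to the fiber mask
#' when one is supplied) and the ratio target/reference is multiplied
#' by 100.
#'
#' @param image a [multichannel_image()].
#' @param roi a `profile_roi` from [select_profile_roi()].
#' @param channels named character vector mapping `target` and `reference`
#'   to channel names in `image`.
#' @param mask optional fiber mask; restricts interpolation support.
#' @return Object of class `raw_profile`: data.frame `data` with
#'   `position_px`, `position_um`, `target_mean`, `reference_mean`, `ratio`,
#'   `n_pixels`, plus the originating `roi`.
#' @export
compute_ratio_profile <- function(image, roi,
                                  channels = c(target = "target",
                                               reference = "reference"),
                                  mask = NULL) {
  stopifnot(inherits(image, "multichannel_image"), inherits(roi, "profile_roi"))
  tgt <- get_channel(image, channels[["target"]])
  ref <- get_channel(image, channels[["reference"]])
  pts <- roi_sample_points(roi)
  tv <- sample_bilinear(tgt, pts[, "x"], pts[, "y"], mask = mask, outside = NA)
  rv <- sample_bilinear(ref, pts[, "x"], pts[, "y"], mask = mask, outside = NA)
  step <- pts[, "step"]
  tm <- tapply(tv, step, mean, na.rm = TRUE)
  rm_ <- tapply(rv, step, mean, na.rm = TRUE)
  npix <- tapply(!is.na(rv), step, sum)
  if (any(!is.finite(rm_)) || any(rm_ <= 0))
    stop("zero-mean reference at some profile positions: widen the box or ",
         "supply a fiber mask", call. = FALSE)
  pos <- as.numeric(names(tm))
  structure(list(data = data.frame(position_px = pos,
                                   position_um = pos * roi$um_per_pixel,
                                   target_mean = as.numeric(tm),
                                   reference_mean = as.numeric(rm_),
                                   ratio = 100 * as.numeric(tm) / as.numeric(rm_),
                                   n_pixels = as.numeric(npix)),
                 roi = roi),
            class = "raw_profile")
}

#' Normalize a profile to the 0-100 position grid
#'
#' Rescales the span so the muscle end is 0 and the nucleus is 100
#' (accounting for positioning defects that change the physical span
#' length), linearly interpolates the ratio onto a fixed 101-point grid,
#' and computes the peak (maximum ratio) and the area under the curve
#' (trapezoidal rule on the normalized axis, the conventional reading of a
#' spreadsheet area calculation).
#'
#' @param raw a `raw_profile` (>= 4 positions) from
#'   [compute_ratio_profile()] , or any data.frame with `position_um` (or
#'   `position_px`) and `ratio`.
#' @param grid_points number of grid points on \[0, 100\].
#' @return Object of class `localization_profile` with `positions`,
#'   `ratio`, `peak`, `auc`, `span_um`, `n_pixels_per_bin`.
#' @export
normalize_profile <- function(raw, grid_points = 101L) {
  df <- if (inherits(raw, "raw_profile")) raw$data else raw
  if (nrow(df) < 4)
    stop("profile span too short: need at least 4 raw positions", call. = FALSE)
  pos <- df$position_um %||% df$position_px
  pct <- (pos - min(pos)) / (max(pos) - min(pos)) * 100
  grid <- seq(0, 100, length.out = grid_points)
  ratio <- stats::approx(pct, df$ratio, xout = grid, rule = 2)$y
  npix <- if (!is.null(df$n_pixels))
    stats::approx(pct, df$n_pixels, xout = grid, rule = 2)$y else rep(NA, grid_points)
  structure(list(positions = grid, ratio = ratio,
                 peak = max(ratio),
                 auc = trapezoid_auc(grid, ratio),
                 span_um = max(pos) - min(pos),
                 n_pixels_per_bin = npix),
            class = "localization_profile")
}

#' @export
print.localization_profile <- function(x, ...) {
  cat(sprintf("<localization_profile> span %.2f um, peak %.1f, AUC %.0f\n",
              x$span_um, x$peak, x$auc))
  invisible(x)
}

#' Fixed-dimension box profile (raw position)
#'
#' For proteins scored near the nucleus rather than over the whole span, a
#' box of fixed physical dimensions is anchored at the nearest-nucleus
#' outline and extends toward the muscle end; ratios are reported against
#' raw micrometre position (0 = nucleus edge), with peak and AUC on the
#' raw axis.
#'
#' @param image a [multichannel_image()].
#' @param fiber a [fiber_geometry()].
#' @param nuclei a [nucleus_set()].
#' @param box_length_um fixed box length.
#' @param width_um box width.
#' @param end which muscle end the box extends toward.
#' @param channels as in [compute_ratio_profile()].
#' @return A `raw_profile` with attributes `peak` and `auc` (raw-axis
#'   trapezoid).
#' @export
fixed_box_profile <- function(image, fiber, nuclei, box_length_um = 5,
                              width_um = 2, end = c("dorsal", "ventral"),
                              channels = c(target = "target",
                                           reference = "reference")) {
  end <- match.arg(end)
  roi0 <- select_profile_roi(fiber, nuclei, end, width_um = width_um)
  span_um <- roi0$length_px * fiber$um_per_pixel
  if (box_length_um > span_um)
    stop(sprintf("fixed box (%.1f um) exceeds the end-to-nucleus span (%.2f um)",
                 box_length_um, span_um), call. = FALSE)
  # anchor at the nucleus-outline endpoint, pointing back toward the end
  origin <- roi0$origin + roi0$dir * roi0$length_px
  roi <- structure(list(origin = origin, dir = -roi0$dir,
                        length_px = box_length_um / fiber$um_per_pixel,
                        width_px = roi0$width_px, end = end,
                        nucleus_id = roi0$nucleus_id,
                        um_per_pixel = fiber$um_per_pixel),
                   class = "profile_roi")
  prof <- compute_ratio_profile(image, roi, channels = channels,
                                mask = fiber$mask)
  attr(prof, "peak") <- max(prof$data$ratio)
  attr(prof, "auc") <- trapezoid_auc(prof$data$position_um, prof$data$ratio)
  prof
}

#' Distal-region intensity ratio
#'
#' Mean target / mean reference x 100 over the mask pixels within
#' `depth_um` of the given muscle end (axial distance), e.g. microtubule
#' signal in the distal 2 um of the fiber.
#'
#' @inheritParams fixed_box_profile
#' @param depth_um distal zone depth.
#' @return Scalar ratio (a.u.).
#' @export
distal_region_ratio <- function(image, fiber, depth_um = 2,
                                end = c("dorsal", "ventral"),
                                channels = c(target = "target",
                                             reference = "reference")) {
  end <- match.arg(end)
  if (fiber$length_um <= depth_um)
    stop("fiber shorter than the distal depth", call. = FALSE)
  idx <- which(fiber$mask, arr.ind = TRUE)
  pts <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  a <- axial_um(fiber, pts)
  dist_from_end <- if (end == "dorsal") a else fiber$length_um - a
  sel <- dist_from_end <= depth_um
  tgt <- get_channel(image, channels[["target"]])
  ref <- get_channel(image, channels[["reference"]])
  lin <- (idx[sel, 2] - 1) * nrow(fiber$mask) + idx[sel, 1]
  100 * mean(tgt[lin]) / mean(ref[lin])
}

#' Average profiles across a cohort
#'
#' Pointwise mean and sample SD of normalized profiles on a common grid,
#' plus cohort statistics: the mean/SD of the per-profile peaks and AUCs
#' (not the peak of the mean curve).
#'
#' @param profiles list of `localization_profile` objects on one grid.
#' @return Object of class `cohort_profile` with `positions`, `mean`, `sd`,
#'   `peak_mean`, `peak_sd`, `auc_mean`, `auc_sd`, `n`, `peaks`, `aucs`.
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) < 2)
    stop("need at least 2 profiles to average", call. = FALSE)
  grids <- lapply(profiles, `[[`, "positions")
  if (!all(vapply(grids, function(g) isTRUE(all.equal(g, grids[[1]])), logical(1))))
    stop("profiles are on mismatched grids: normalize first", call. = FALSE)
  mat <- do.call(rbind, lapply(profiles, `[[`, "ratio"))
  peaks <- vapply(profiles, `[[`, numeric(1), "peak")
  aucs <- vapply(profiles, `[[`, numeric(1), "auc")
  structure(list(positions = grids[[1]],
                 mean = colMeans(mat),
                 sd = apply(mat, 2, stats::sd),
                 peak_mean = mean(peaks), peak_sd = stats::sd(peaks),
                 auc_mean = mean(aucs), auc_sd = stats::sd(aucs),
                 n = length(profiles), peaks = peaks, aucs = aucs),
            class = "cohort_profile")
}

# Per-profile total of the reference channel alone on the normalized axis.
reference_total <- function(raw) {
  df <- raw$data
  pct <- (df$position_um - min(df$position_um)) /
    (max(df$position_um) - min(df$position_um)) * 100
  trapezoid_auc(pct, df$reference_mean)
}

#' Reference-channel control check
#'
#' Verifies that the reference (structural) stain does not differ between
#' genotypes, which is the precondition for using it as the ratio
#' denominator. Per-profile reference totals are compared between each
#' genotype and the control by the dual-significance rule (pairwise
#' Student's t-test and one-way ANOVA across all genotypes must both
#' pass).
#'
#' @param profiles_by_genotype named list; each element is a list of
#'   `raw_profile` objects for one genotype.
#' @param control name of the control genotype (default: first element).
#' @param alpha significance threshold for flagging.
#' @return data.frame with one row per non-control genotype: mean, sd, n,
#'   `p_t`, `p_anova`, `flagged`, `stars`.
#' @export
reference_control_check <- function(profiles_by_genotype, control = NULL,
                                    alpha = 0.05) {
  if (length(profiles_by_genotype) < 2)
    stop("need at least 2 genotypes to compare reference levels", call. = FALSE)
  control <- control %||% names(profiles_by_genotype)[1]
  totals <- lapply(profiles_by_genotype, function(pl)
    vapply(pl, reference_total, numeric(1)))
  p_anova <- one_way_anova(totals)$p_value
  others <- setdiff(names(totals), control)
  do.call(rbind, lapply(others, function(g) {
    tt <- students_t(totals[[g]], totals[[control]])
    dual <- dual_significance(tt$p_value, p_anova)
    data.frame(genotype = g, mean = mean(totals[[g]]),
               sd = stats::sd(totals[[g]]), n = length(totals[[g]]),
               p_t = tt$p_value, p_anova = p_anova,
               flagged = dual$significant_05, stars = dual$stars)
  }))
}
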