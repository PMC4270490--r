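#' Fiber geometry
#'
#' A `fiber_geometry` describes one elongated muscle fiber: its binary mask,
#' long-axis direction, the two end contours ("dorsal" is the end with the
#' smaller axial coordinate by convention), and its physical length. Axial
#' position runs from 0 at the dorsal end to `length_um` at the ventral end.
#'
#' Coordinates are pixel-centered and 0-based (`x = column - 1`,
#' `y = row - 1`, y increasing downward); physical units are micrometres via
#' `um_per_pixel`.
#'
#' @param mask logical matrix, `TRUE` inside the fiber.
#' @param um_per_pixel pixel size in micrometres.
#' @param axis unit 2-vector of the long axis (dorsal to ventral).
#' @param width_um nominal fiber width in micrometres (may be estimated).
#' @param orientation_deg long-axis orientation in degrees, if known.
#' @param flip_dorsal set `TRUE` to swap the dorsal/ventral labeling.
#' @return An object of class `fiber_geometry`.
#' @export
fiber_geometry <- function(mask, um_per_pixel, axis, width_um = NA_real_,
                           orientation_deg = NA_real_, flip_dorsal = FALSE) {
  stopifnot(is.matrix(mask))
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  mask <- mask != 0
  if (!any(mask)) stop("empty fiber mask", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  if (flip_dorsal) axis <- -axis
  idx <- which(mask, arr.ind = TRUE)
  px <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)
  s <- px %*% axis
  s_min <- min(s); s_max <- max(s)
  length_px <- (s_max - s_min) + 1    # pixel extent + 1 px
  # end contours: mask pixels within 1 px of each axial extreme
  dorsal <- px[s < s_min + 1, , drop = FALSE]
  ventral <- px[s > s_max - 1, , drop = FALSE]
  v <- c(-axis[2], axis[1])
  t_all <- px %*% v
  width_px_est <- (max(t_all) - min(t_all)) + 1
  obj <- structure(list(
    mask = mask,
    um_per_pixel = um_per_pixel,
    axis = as.numeric(axis),
    s_min = as.numeric(s_min),
    t_mid = as.numeric((max(t_all) + min(t_all)) / 2),
    length_px = as.numeric(length_px),
    length_um = as.numeric(length_px * um_per_pixel),
    width_um = if (is.na(width_um)) as.numeric(width_px_est * um_per_pixel) else width_um,
    orientation_deg = orientation_deg,
    end_contours = list(dorsal = dorsal, ventral = ventral)
  ), class = "fiber_geometry")
  if (obj$length_um <= 1.5 * obj$width_um)
    warning("fiber length is close to its width: long-axis orientation is poorly defined",
            call. = FALSE)
  obj
}

#' @export
print.fiber_geometry <- function(x, ...) {
  cat(sprintf("<fiber_geometry> %.1f um x %.1f um, %.3g um/px, axis (%.3f, %.3f)\n",
              x$length_um, x$width_um, x$um_per_pixel, x$axis[1], x$axis[2]))
  invisible(x)
}

#' Derive fiber geometry from a binary mask
#'
#' Estimates the long axis as the principal eigenvector of the in-mask pixel
#' coordinate covariance, then builds a [fiber_geometry()]. The dorsal end is
#' the end with the smaller axial coordinate under a canonical axis sign
#' (positive x component, ties broken toward positive y); use `flip_dorsal`
#' to reverse the labeling.
#'
#' @param mask logical or 0/1 matrix.
#' @param um_per_pixel pixel size in micrometres.
#' @param flip_dorsal swap dorsal/ventral labels.
#' @return A [fiber_geometry()].
#' @export
fiber_from_mask <- function(mask, um_per_pixel, flip_dorsal = FALSE) {
  mask <- mask != 0
  if (!any(mask)) stop("empty fiber mask", call. = FALSE)
  idx <- which(mask, arr.ind = TRUE)
  px <- cbind(idx[, 2] - 1, idx[, 1] - 1)
  cv <- stats::cov(px)
  eg <- eigen(cv, symmetric = TRUE)
  u <- eg$vectors[, 1]
  if (u[1] < 0 || (u[1] == 0 && u[2] < 0)) u <- -u
  fiber_geometry(mask, um_per_pixel, axis = u, flip_dorsal = flip_dorsal)
}

# Axial coordinate in um of pixel points (matrix with columns x, y),
# measured from the dorsal fiber edge (0) to the ventral edge (length_um).
axial_um <- function(fiber, pts) {
  s <- pts[, 1] * fiber$axis[1] + pts[, 2] * fiber$axis[2]
  (s - fiber$s_min + 0.5) * fiber$um_per_pixel
}

# Signed perpendicular offset in um from the fiber midline.
perp_um <- function(fiber, pts) {
  v <- c(-fiber$axis[2], fiber$axis[1])
  t <- pts[, 1] * v[1] + pts[, 2] * v[2]
  (t - fiber$t_mid) * fiber$um_per_pixel
}

# Inverse map: fiber-local (axial um, perpendicular um) -> pixel coordinates.
local_to_px <- function(fiber, a_um, t_um) {
  u <- fiber$axis; v <- c(-u[2], u[1])
  s <- fiber$s_min + a_um / fiber$um_per_pixel - 0.5
  t <- fiber$t_mid + t_um / fiber$um_per_pixel
  cbind(x = s * u[1] + t * v[1], y = s * u[2] + t * v[2])
}

#' Nucleus set
#'
#' A labeled collection of nucleus outlines and centroids within one fiber.
#' Each nucleus is a list with `id`, `centroid_px` (x, y), `outline` (polygon
#' matrix with columns x, y, pixel coordinates), and `area_px`.
#'
#' @param nuclei list of nucleus entries (see Details).
#' @param um_per_pixel pixel size in micrometres.
#' @return An object of class `nucleus_set`.
#' @export
nucleus_set <- function(nuclei, um_per_pixel) {
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  for (nuc in nuclei) {
    if (is.null(nuc$id) || is.null(nuc$centroid_px) || is.null(nuc$outline))
      stop("each nucleus needs id, centroid_px and outline", call. = FALSE)
    if (!is.null(nuc$area_px) && nuc$area_px <= 0)
      stop("nucleus areas must be positive", call. = FALSE)
  }
  structure(list(nuclei = nuclei, um_per_pixel = um_per_pixel),
            class = "nucleus_set")
}

#' @export
length.nucleus_set <- function(x) length(x$nuclei)

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d nuclei, %.3g um/px\n", length(x), x$um_per_pixel))
  invisible(x)
}

#' @export
as.data.frame.nucleus_set <- function(x, ...) {
  do.call(rbind, lapply(x$nuclei, function(n) {
    data.frame(nucleus_id = n$id, x_px = n$centroid_px[1], y_px = n$centroid_px[2],
               area_px = n$area_px %||% NA_real_)
  }))
}

nucleus_centroids_px <- function(nuclei) {
  do.call(rbind, lapply(nuclei$nuclei, function(n) n$centroid_px))
}
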