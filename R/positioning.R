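#' End-to-nucleus distance
#'
#' Shortest boundary-to-boundary Euclidean distance between the indicated
#' muscle end contour and the nearest nucleus outline, normalized to muscle
#' length. Boundary distance (rather than centroid or purely axial distance)
#' matches how the span is drawn between the muscle end and the nucleus
#' body.
#'
#' @param fiber a [fiber_geometry()].
#' @param nuclei a [nucleus_set()] (at least one nucleus).
#' @param end `"dorsal"` or `"ventral"`.
#' @return List with `normalized` (distance / muscle length), `distance_um`,
#'   and `nucleus_id` of the nearest nucleus.
#' @export
end_to_nucleus_distance <- function(fiber, nuclei, end = c("dorsal", "ventral")) {
  end <- match.arg(end)
  if (length(nuclei) < 1)
    stop("end-to-nucleus distance needs at least one nucleus", call. = FALSE)
  contour <- fiber$end_contours[[end]]
  best <- Inf; best_id <- NA_integer_
  for (n in nuclei$nuclei) {
    d2 <- outer(contour[, 1], n$outline[, 1], `-`)^2 +
      outer(contour[, 2], n$outline[, 2], `-`)^2
    d <- sqrt(min(d2)) * fiber$um_per_pixel
    if (d < best) { best <- d; best_id <- n$id }
  }
  list(normalized = best / fiber$length_um, distance_um = best,
       nucleus_id = best_id)
}

#' Nearest-neighbor distances between nuclei
#'
#' For each nucleus, the minimum centroid-to-centroid Euclidean distance to
#' any other nucleus, normalized to muscle length.
#'
#' @inheritParams end_to_nucleus_distance
#' @return Numeric vector (one value per nucleus, in nucleus order).
#' @export
nearest_neighbor_distances <- function(fiber, nuclei) {
  if (length(nuclei) < 2)
    stop("nearest-neighbor distance is undefined (not zero) with fewer ",
         "than 2 nuclei", call. = FALSE)
  ctr <- nucleus_centroids_px(nuclei)
  dm <- as.matrix(stats::dist(ctr)) * fiber$um_per_pixel
  diag(dm) <- Inf
  apply(dm, 1, min) / fiber$length_um
}

#' Longest nucleus-free gap
#'
#' Projects each nucleus outline onto the fiber long axis as a covered
#' interval, merges the intervals, and returns the longest uncovered
#' sub-interval of the fiber axis, normalized to muscle length. The fiber
#' ends count as gap boundaries, so a nucleus-free muscle end scores as a
#' gap.
#'
#' @inheritParams end_to_nucleus_distance
#' @return Normalized gap length in \[0, 1\].
#' @export
longest_gap <- function(fiber, nuclei) {
  if (length(nuclei) < 1)
    stop("longest gap needs at least one nucleus", call. = FALSE)
  L <- fiber$length_um
  iv <- t(vapply(nuclei$nuclei, function(n) {
    a <- axial_um(fiber, n$outline)
    c(max(0, min(a)), min(L, max(a)))
  }, numeric(2)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  gap <- iv[1, 1]               # dorsal end to first nucleus
  hi <- iv[1, 2]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[i, 1] > hi) gap <- max(gap, iv[i, 1] - hi)
      hi <- max(hi, iv[i, 2])
    }
  }
  gap <- max(gap, L - hi)       # last nucleus to ventral end
  gap / L
}

#' Count nuclei
#'
#' @param nuclei a [nucleus_set()].
#' @return Integer count.
#' @export
count_nuclei <- function(nuclei) length(nuclei)

#' Muscle length along the long axis
#'
#' Extent of the mask pixel centers projected on the fiber axis, plus one
#' pixel, in micrometres. Warns when the mask is nearly as wide as it is
#' long (the long axis is then poorly defined); the warning is raised at
#' construction time by [fiber_geometry()].
#'
#' @param fiber a [fiber_geometry()].
#' @return Length in micrometres.
#' @export
muscle_length <- function(fiber) fiber$length_um

#' All positioning metrics for one fiber, tidy
#'
#' @inheritParams end_to_nucleus_distance
#' @param fiber_id label for the output rows.
#' @return data.frame with columns `fiber_id`, `metric`, `value`,
#'   `normalized_by`. Nearest-neighbor values are summarized by their mean;
#'   per-nucleus values are available from [nearest_neighbor_distances()].
#' @export
position_report <- function(fiber, nuclei, fiber_id = "fiber1") {
  rows <- list(
    c("end_distance_dorsal",
      end_to_nucleus_distance(fiber, nuclei, "dorsal")$normalized, "muscle_length"),
    c("end_distance_ventral",
      end_to_nucleus_distance(fiber, nuclei, "ventral")$normalized, "muscle_length"),
    c("longest_gap", longest_gap(fiber, nuclei), "muscle_length"),
    c("n_nuclei", count_nuclei(nuclei), "none"),
    c("muscle_length_um", muscle_length(fiber), "none"))
  if (length(nuclei) >= 2)
    rows <- append(rows, list(c("nn_distance_mean",
                                mean(nearest_neighbor_distances(fiber, nuclei)),
                                "muscle_length")), after = 2)
  data.frame(fiber_id = fiber_id,
             metric = vapply(rows, `[`, character(1), 1),
             value = as.numeric(vapply(rows, `[`, character(1), 2)),
             normalized_by = vapply(rows, `[`, character(1), 3))
}
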