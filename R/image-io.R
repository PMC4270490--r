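#' Multi-channel image
#'
#' Named list of equally sized intensity matrices with a physical pixel
#' calibration. Intensities are unitless arbitrary units; no flat-field or
#' bleaching correction is applied anywhere in the package.
#'
#' @param channels named list of numeric matrices (same dimensions).
#' @param um_per_pixel pixel size in micrometres.
#' @return Object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, um_per_pixel) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(names(channels) == ""))
    stop("channels must be named", call. = FALSE)
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share dimensions", call. = FALSE)
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  structure(list(channels = channels, um_per_pixel = um_per_pixel),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<multichannel_image> %d x %d px, %.3g um/px, channels: %s\n",
              d[1], d[2], x$um_per_pixel, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

get_channel <- function(image, name) {
  ch <- image$channels[[name]]
  if (is.null(ch))
    stop(sprintf("channel '%s' not found; available: %s", name,
                 paste(names(image$channels), collapse = ", ")), call. = FALSE)
  ch
}

#' Write a multi-channel image as TIFF
#'
#' One 32-bit float page per channel, lossless. Channel names and the pixel
#' calibration are stored in a JSON sidecar (`<path>.json`), since baseline
#' TIFF tags cannot carry them portably.
#'
#' @param image a [multichannel_image()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "multichannel_image"))
  # baseline float TIFF stores [0, 1]; rescale per channel and record the
  # scale in the sidecar so intensities round-trip
  scales <- vapply(image$channels, function(m) max(1, max(m)), numeric(1))
  pages <- Map(function(m, s) m / s, image$channels, scales)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(channels = names(image$channels),
                            scales = unname(scales),
                            um_per_pixel = image$um_per_pixel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel TIFF
#'
#' Pages become channels. Channel names come from the JSON sidecar written
#' by [write_image()] when present, otherwise from `channel_map` (a named
#' list/vector mapping role -> page index, e.g.
#' `list(reference = 1, nuclei = 2, target = 3)`).
#'
#' @param path TIFF file.
#' @param channel_map named page assignment; required if no sidecar exists.
#' @param um_per_pixel overrides the calibration; if absent everywhere,
#'   defaults to 1 with a warning.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, channel_map = NULL, um_per_pixel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # collapse grayscale-as-RGB pages
    p
  })
  meta <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!is.null(meta$scales) && length(meta$scales) == length(pages))
    pages <- Map(function(p, s) p * s, pages, meta$scales)
  if (!is.null(channel_map)) {
    idx <- unlist(channel_map)
    bad <- idx[idx > length(pages) | idx < 1]
    if (length(bad))
      stop(sprintf("channel_map names page(s) %s but file has %d page(s)",
                   paste(bad, collapse = ", "), length(pages)), call. = FALSE)
    channels <- lapply(idx, function(i) pages[[i]])
    names(channels) <- names(channel_map)
  } else if (!is.null(meta$channels) && length(meta$channels) == length(pages)) {
    channels <- pages
    names(channels) <- meta$channels
  } else {
    channels <- pages
    names(channels) <- paste0("channel", seq_along(pages))
  }
  upp <- um_per_pixel %||% meta$um_per_pixel
  if (is.null(upp)) {
    warning("no pixel calibration found; defaulting to 1 um/px", call. = FALSE)
    upp <- 1
  }
  multichannel_image(channels, upp)
}

#' Maximum-intensity projection
#'
#' Per-pixel maximum over Z, per channel. Accepts either a list of
#' [multichannel_image()] slices (a Z-stack) or a single image (returned
#' unchanged, which makes the projection idempotent).
#'
#' @param stack list of [multichannel_image()] slices sharing channels and
#'   calibration, or one image.
#' @return A [multichannel_image()].
#' @export
max_project <- function(stack) {
  if (inherits(stack, "multichannel_image")) return(stack)
  stopifnot(is.list(stack), length(stack) >= 1,
            all(vapply(stack, inherits, logical(1), "multichannel_image")))
  if (length(stack) == 1) return(stack[[1]])
  ch_names <- names(stack[[1]]$channels)
  channels <- lapply(ch_names, function(nm) {
    Reduce(pmax, lapply(stack, function(sl) get_channel(sl, nm)))
  })
  names(channels) <- ch_names
  multichannel_image(channels, stack[[1]]$um_per_pixel)
}

#' Segment fiber and nuclei from an image or use provided masks
#'
#' Automatic mode thresholds the reference channel by Otsu's method and
#' keeps the largest connected component as the fiber mask, then thresholds
#' the nuclei channel and keeps connected components of at least
#' `min_nucleus_area_px`. This emulates (coarsely) the manual outlining the
#' measurements assume; hand-drawn masks via `method = "provided"` are the
#' reference route.
#'
#' @param x a [multichannel_image()] (for `method = "otsu"`), or a list with
#'   `fiber_mask` and `nucleus_labels` matrices (for `method = "provided"`).
#' @param method `"otsu"` or `"provided"`.
#' @param min_nucleus_area_px discard smaller nuclear components.
#' @return Object of class `segmentation` with `fiber_mask` (logical
#'   matrix), `nucleus_labels` (integer matrix), and `source`.
#' @export
load_segmentation <- function(x, method = c("otsu", "provided"),
                              min_nucleus_area_px = 20) {
  method <- match.arg(method)
  if (method == "provided") {
    stopifnot(is.list(x), !is.null(x$fiber_mask), !is.null(x$nucleus_labels))
    seg <- structure(list(fiber_mask = x$fiber_mask != 0,
                          nucleus_labels = x$nucleus_labels,
                          source = "provided"), class = "segmentation")
  } else {
    stopifnot(inherits(x, "multichannel_image"))
    ref <- get_channel(x, "reference")
    nuc <- get_channel(x, "nuclei")
    if (max(ref) <= 0 || max(nuc) <= 0)
      stop("cannot segment: a required channel is entirely zero", call. = FALSE)
    thr_r <- EBImage::otsu(EBImage::Image(t(ref / max(ref))), range = c(0, 1))
    lab_r <- EBImage::bwlabel(EBImage::Image(t(ref / max(ref) > thr_r)))
    labs <- as.integer(t(EBImage::imageData(lab_r)))
    if (all(labs == 0)) stop("empty fiber mask after thresholding", call. = FALSE)
    counts <- tabulate(labs[labs > 0])
    fiber_mask <- matrix(labs == which.max(counts), nrow(ref), ncol(ref))
    thr_n <- EBImage::otsu(EBImage::Image(t(nuc / max(nuc))), range = c(0, 1))
    lab_n <- EBImage::bwlabel(EBImage::Image(t(nuc / max(nuc) > thr_n)))
    nl <- matrix(as.integer(t(EBImage::imageData(lab_n))), nrow(nuc), ncol(nuc))
    areas <- tabulate(nl[nl > 0])
    keep <- which(areas >= min_nucleus_area_px)
    relab <- integer(max(nl, 1)); relab[keep] <- seq_along(keep)
    nl[nl > 0] <- relab[nl[nl > 0]]
    seg <- structure(list(fiber_mask = fiber_mask, nucleus_labels = nl,
                          source = "derived"), class = "segmentation")
  }
  protr <- seg$nucleus_labels > 0 & !seg$fiber_mask
  n_nuc_px <- sum(seg$nucleus_labels > 0)
  if (n_nuc_px > 0) {
    frac <- sum(protr) / n_nuc_px
    if (frac > 0.05)
      stop(sprintf("nucleus labels protrude %.1f%% outside the fiber mask; ",
                   100 * frac), "check the segmentation inputs", call. = FALSE)
    if (frac > 0)
      warning(sprintf("nucleus labels protrude %.2f%% outside the fiber mask",
                      100 * frac), call. = FALSE)
  }
  seg
}

#' Nucleus set from a label image
#'
#' Builds outlines (via contour tracing) and centroids for each labeled
#' nuclear component.
#'
#' @param labels integer label matrix (0 = background).
#' @param um_per_pixel pixel size in micrometres.
#' @return A [nucleus_set()].
#' @export
nuclei_from_labels <- function(labels, um_per_pixel) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(nucleus_set(list(), um_per_pixel))
  oc <- EBImage::ocontour(EBImage::Image(t(labels)))
  nuclei <- lapply(seq_along(ids), function(k) {
    id <- ids[k]
    idx <- which(labels == id, arr.ind = TRUE)
    ctr <- c(mean(idx[, 2] - 1), mean(idx[, 1] - 1))
    # ocontour coordinates are (x, y) in the transposed image, 0-based
    poly <- oc[[id]]
    outline <- cbind(x = poly[, 1], y = poly[, 2])
    list(id = k, centroid_px = ctr, outline = outline, area_px = nrow(idx))
  })
  nucleus_set(nuclei, um_per_pixel)
}
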