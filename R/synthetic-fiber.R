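#' Generate an elongated fiber mask
#'
#' Builds the binary mask and geometry of a synthetic muscle fiber: a
#' rotated rectangle of the requested physical size, rasterized on a pixel
#' grid with a small background margin. The end with the smaller axial
#' coordinate is labeled "dorsal".
#'
#' @param length_um fiber length along the long axis (must exceed the width).
#' @param width_um fiber width.
#' @param um_per_pixel pixel size in micrometres.
#' @param orientation_deg long-axis orientation (0 = horizontal).
#' @param margin_um background margin around the fiber.
#' @return A [fiber_geometry()].
#' @export
#' @examples
#' f <- make_fiber(40, 6, 0.2)
#' f$length_um
make_fiber <- function(length_um, width_um, um_per_pixel,
                       orientation_deg = 0, margin_um = 2) {
  stop_if_not_scalar_pos(um_per_pixel, "um_per_pixel")
  if (!is.numeric(length_um) || !is.numeric(width_um) ||
      width_um <= 0 || length_um <= width_um)
    stop("need length_um > width_um > 0", call. = FALSE)
  if (width_um / um_per_pixel < 4)
    stop("degenerate fiber: mask would be under 4 pixels across; ",
         "use a smaller um_per_pixel or a wider fiber", call. = FALSE)
  L <- length_um / um_per_pixel
  W <- width_um / um_per_pixel
  th <- orientation_deg * pi / 180
  u <- c(cos(th), sin(th))
  v <- c(-sin(th), cos(th))
  m <- max(4, ceiling(margin_um / um_per_pixel))
  hx <- abs(u[1]) * L / 2 + abs(v[1]) * W / 2
  hy <- abs(u[2]) * L / 2 + abs(v[2]) * W / 2
  nx <- ceiling(2 * hx) + 2 * m
  ny <- ceiling(2 * hy) + 2 * m
  cx <- (nx - 1) / 2
  cy <- (ny - 1) / 2
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx) - cx
  y <- matrix(rep(0:(ny - 1), times = nx), ny, nx) - cy
  s <- x * u[1] + y * u[2]
  t <- x * v[1] + y * v[2]
  mask <- s >= -L / 2 & s < L / 2 & t >= -W / 2 & t < W / 2
  fiber_geometry(mask, um_per_pixel, axis = u, width_um = width_um,
                 orientation_deg = orientation_deg)
}

#' Place nuclei inside a fiber under a genotype preset
#'
#' Draws nucleus axial positions from the preset's Gaussian cluster mixture
#' (clusters are filled round-robin so counts balance) with a small
#' perpendicular jitter, then rejects and resamples any placement that would
#' overlap an accepted nucleus or leave the fiber. Placement happens in
#' fiber-local coordinates, so identical seeds give identical physical
#' placements regardless of raster orientation or pixel size.
#'
#' @param fiber a [fiber_geometry()].
#' @param preset a [genotype_preset()].
#' @param seed integer seed for reproducible placement.
#' @param max_tries rejection-sampling budget per nucleus.
#' @param min_gap_um minimum clearance enforced between nucleus outlines.
#'   A standoff between nuclei and the fiber ends (preset field
#'   `nucleus_placement$end_clearance_um`, default 2) keeps an
#'   end-to-nucleus span defined even for end-clustered genotypes.
#' @return A [nucleus_set()]; nuclei are ordered (and ids assigned) by
#'   ascending axial position. The fractional axial position of each nucleus
#'   is stored as `frac_position`.
#' @export
place_nuclei <- function(fiber, preset, seed = NULL, max_tries = 2000L,
                         min_gap_um = 0.4) {
  stopifnot(inherits(fiber, "fiber_geometry"), inherits(preset, "genotype_preset"))
  with_seed_if(seed, {
    np <- preset$nucleus_placement
    sh <- preset$nucleus_shape
    a <- sh$semi_major_um
    b <- sh$semi_minor_um
    L <- fiber$length_um
    k <- length(np$cluster_centers)
    clearance <- preset$nucleus_placement$end_clearance_um %||% 2.0
    margin_frac <- (a + clearance + fiber$um_per_pixel) / L
    tmax <- fiber$width_um / 2 - b - 0.2
    if (tmax < 0)
      stop("nuclei do not fit inside the fiber: fiber too narrow for the ",
           "preset nucleus size", call. = FALSE)
    acc_a <- numeric(0); acc_t <- numeric(0)
    n_restarts <- 20L
    for (restart in seq_len(n_restarts)) {
      acc_a <- numeric(0); acc_t <- numeric(0)
      failed_at <- 0L
      for (i in seq_len(np$n_nuclei)) {
        ctr <- np$cluster_centers[((i - 1) %% k) + 1]
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          f <- stats::rnorm(1, ctr, np$cluster_sd)
          f <- min(max(f, margin_frac), 1 - margin_frac)
          t_off <- if (tmax > 0) {
            max(-tmax, min(tmax, stats::rnorm(1, 0, 0.9)))
          } else 0
          a_um <- f * L
          # clearance test against the Minkowski-style contact ellipse of two
          # axis-aligned equal ellipses, inflated by min_gap_um
          ok <- all(((acc_a - a_um) / (2 * a + min_gap_um))^2 +
                      ((acc_t - t_off) / (2 * b + min_gap_um))^2 >= 1)
          if (ok) {
            acc_a <- c(acc_a, a_um); acc_t <- c(acc_t, t_off)
            placed <- TRUE
            break
          }
        }
        if (!placed) { failed_at <- i; break }
      }
      if (failed_at == 0L) break
      if (restart == n_restarts)
        stop(sprintf(paste0("could not place nucleus %d of %d without overlap ",
                            "(%d tries x %d restarts): nucleus density too ",
                            "high for the fiber/cluster geometry"),
                     failed_at, np$n_nuclei, max_tries, n_restarts),
             call. = FALSE)
    }
    ord <- order(acc_a)
    acc_a <- acc_a[ord]; acc_t <- acc_t[ord]
    nuclei <- lapply(seq_along(acc_a), function(i) {
      ctr_px <- local_to_px(fiber, acc_a[i], acc_t[i])
      outline <- ellipse_polygon(as.numeric(ctr_px),
                                 a / fiber$um_per_pixel,
                                 b / fiber$um_per_pixel,
                                 fiber$axis)
      list(id = i,
           centroid_px = as.numeric(ctr_px),
           outline = outline,
           area_px = pi * (a / fiber$um_per_pixel) * (b / fiber$um_per_pixel),
           frac_position = acc_a[i] / L,
           semi_major_um = a,
           semi_minor_um = b,
           t_um = acc_t[i])
    })
    nucleus_set(nuclei, fiber$um_per_pixel)
  })
}

#' Analytic truth ratio curve for a preset
#'
#' Returns the noiseless (target/reference) x 100 ratio as a function of
#' normalized position along an end-to-nearest-nucleus span (0 = muscle end,
#' 100 = nucleus). The span length cancels in the model, so one curve serves
#' both fiber ends.
#'
#' @param preset a [genotype_preset()].
#' @return Function mapping positions in \[0, 100\] to ratio values.
#' @export
truth_ratio_fun <- function(preset) {
  tm <- preset$target_model
  ref <- preset$reference_level
  w <- tm$mixture_weight_diffuse
  function(pos_pct) {
    x <- pos_pct / 100
    peaked <- tm$baseline +
      tm$peak_amplitude * exp(-abs(x - tm$peak_position) / tm$decay_length)
    diffuse <- tm$baseline + 0.5 * tm$peak_amplitude
    100 / ref * ((1 - w) * peaked + w * diffuse)
  }
}

# Noiseless target-channel intensity at axial position a_um, given the two
# end-to-nearest-nucleus span lengths. Interior pixels (past both spans)
# carry the at-nucleus value so the field is continuous. Span position 0
# sits at the terminal pixel center (where a measurement box anchors), not
# at the physical fiber edge half a pixel further out.
target_intensity_at <- function(a_um, L_um, span_dorsal, span_ventral, preset) {
  tm <- preset$target_model
  w <- tm$mixture_weight_diffuse
  x <- rep(1, length(a_um))
  from_v <- L_um - a_um
  in_d <- a_um <= span_dorsal
  in_v <- !in_d & from_v <= span_ventral
  x[in_d] <- a_um[in_d] / span_dorsal
  x[in_v] <- from_v[in_v] / span_ventral
  x <- pmin(pmax(x, 0), 1)   # clamp: the model lives on the span
  peaked <- tm$baseline +
    tm$peak_amplitude * exp(-abs(x - tm$peak_position) / tm$decay_length)
  diffuse <- tm$baseline + 0.5 * tm$peak_amplitude
  (1 - w) * peaked + w * diffuse
}

# End-to-nearest-nucleus axial span lengths in um, measured from the
# terminal pixel centers (half a pixel inside the physical fiber edge) to
# the nearest nucleus outline, matching what a profile box can measure.
nucleus_spans <- function(fiber, nuclei) {
  proj <- lapply(nuclei$nuclei, function(n) range(axial_um(fiber, n$outline)))
  lo <- min(vapply(proj, `[`, numeric(1), 1))
  hi <- max(vapply(proj, `[`, numeric(1), 2))
  half <- fiber$um_per_pixel / 2
  eps <- fiber$um_per_pixel
  list(dorsal = max(lo - half, eps),
       ventral = max((fiber$length_um - half) - hi, eps))
}

#' Render synthetic fluorescence channels
#'
#' Rasterizes the three channels of a synthetic fiber: a reference channel
#' (uniform `reference_level` inside the mask, emulating a structural stain),
#' a nuclei channel (bright ellipses), and a target channel following the
#' preset's end-to-nucleus intensity model. Noise is applied last; with the
#' noise level at zero the rendered ratio equals the analytic truth curve.
#'
#' @param fiber a [fiber_geometry()].
#' @param nuclei a [nucleus_set()] placed inside `fiber`.
#' @param preset a [genotype_preset()].
#' @param seed integer seed for the noise draw.
#' @param nucleus_level intensity of the nuclei channel inside nuclei (a.u.).
#' @return List with `image` (a [multichannel_image()] with channels
#'   `reference`, `nuclei`, `target`) and `truth` (class
#'   `synthetic_fiber_truth`: the analytic ratio curve sampled on the
#'   0..100 grid, the truth function, span lengths, and sorted fractional
#'   nucleus positions).
#' @export
render_channels <- function(fiber, nuclei, preset, seed = NULL,
                            nucleus_level = 500) {
  stopifnot(inherits(fiber, "fiber_geometry"), inherits(nuclei, "nucleus_set"))
  with_seed_if(seed, {
    mask <- fiber$mask
    ny <- nrow(mask); nx <- ncol(mask)
    x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
    y <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
    pts <- cbind(as.vector(x), as.vector(y))
    a_um <- axial_um(fiber, pts)
    t_um <- perp_um(fiber, pts)
    spans <- nucleus_spans(fiber, nuclei)

    ref <- matrix(0, ny, nx)
    ref[mask] <- preset$reference_level

    half <- fiber$um_per_pixel / 2
    tgt_vals <- target_intensity_at(a_um - half, fiber$length_um - 2 * half,
                                    spans$dorsal, spans$ventral, preset)
    tgt <- matrix(0, ny, nx)
    tgt[mask] <- tgt_vals[as.vector(mask)]

    nuc <- matrix(0, ny, nx)
    for (n in nuclei$nuclei) {
      da <- a_um - n$frac_position * fiber$length_um
      dt <- t_um - n$t_um
      inside <- (da / n$semi_major_um)^2 + (dt / n$semi_minor_um)^2 <= 1
      nuc[matrix(inside, ny, nx)] <- nucleus_level
    }

    gs <- preset$noise$gaussian_sd
    if (gs > 0) {
      noisy <- function(m) {
        sd_m <- if (isTRUE(preset$noise$poisson_like)) sqrt(gs^2 + m) else
          matrix(gs, nrow(m), ncol(m))
        pmax(m + stats::rnorm(length(m), 0, 1) * sd_m, 0)
      }
      ref <- noisy(ref); tgt <- noisy(tgt); nuc <- noisy(nuc)
    }

    grid <- seq(0, 100, length.out = 101L)
    fn <- truth_ratio_fun(preset)
    truth <- structure(list(
      positions = grid,
      ratio = fn(grid),
      ratio_fun = fn,
      span_dorsal_um = spans$dorsal,
      span_ventral_um = spans$ventral,
      nuclei_frac_positions = vapply(nuclei$nuclei, `[[`, numeric(1),
                                     "frac_position"),
      seed = seed
    ), class = "synthetic_fiber_truth")
    list(image = multichannel_image(list(reference = ref, nuclei = nuc,
                                         target = tgt),
                                    fiber$um_per_pixel),
         truth = truth)
  })
}

#' Generate one complete synthetic fiber
#'
#' Convenience wrapper: [make_fiber()] + [place_nuclei()] +
#' [render_channels()], all under one seed.
#'
#' @inheritParams make_fiber
#' @inheritParams place_nuclei
#' @param render if `FALSE`, skip channel rendering (geometry and nuclei only).
#' @return List with `fiber`, `nuclei`, and (if rendered) `image`, `truth`.
#' @export
simulate_fiber <- function(preset, length_um = 40, width_um = 6,
                           um_per_pixel = 0.2, orientation_deg = 0,
                           seed = NULL, render = TRUE) {
  fiber <- make_fiber(length_um, width_um, um_per_pixel, orientation_deg)
  nuclei <- place_nuclei(fiber, preset, seed = seed)
  out <- list(fiber = fiber, nuclei = nuclei)
  if (render) {
    rc <- render_channels(fiber, nuclei, preset,
                          seed = if (is.null(seed)) NULL else seed + 1L)
    out$image <- rc$image
    out$truth <- rc$truth
  }
  out
}
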