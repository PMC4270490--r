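presets <- default_genotype_presets()

# a single circular nucleus at a chosen axial fraction, for closed forms
single_nucleus_fiber <- function(frac, radius_um = 1.2, um_per_pixel = 0.2) {
  fiber <- make_fiber(40, 6, um_per_pixel)
  ctr <- myoquant:::local_to_px(fiber, frac * fiber$length_um, 0)
  outline <- myoquant:::ellipse_polygon(as.numeric(ctr),
                                        radius_um / um_per_pixel,
                                        radius_um / um_per_pixel,
                                        fiber$axis, n = 256L)
  nuclei <- nucleus_set(list(list(id = 1L, centroid_px = as.numeric(ctr),
                                  outline = outline,
                                  area_px = pi * (radius_um / um_per_pixel)^2)),
                        um_per_pixel)
  list(fiber = fiber, nuclei = nuclei)
}

test_that("end distance of a centered circular nucleus matches the closed form", {
  fx <- single_nucleus_fiber(0.5, radius_um = 1.2)
  d <- end_to_nucleus_distance(fx$fiber, fx$nuclei, "dorsal")
  L <- fx$fiber$length_um
  # dorsal contour pixel centers sit half a pixel inside the fiber edge
  expected <- (0.5 * L - 1.2 - 0.1) / L
  expect_equal(d$normalized, expected, tolerance = 0.2 / L)
  expect_equal(d$nucleus_id, 1L)
  expect_error(end_to_nucleus_distance(fx$fiber,
                                       nucleus_set(list(), 0.2), "dorsal"),
               "at least one")
})

test_that("a nucleus touching the end contour gives distance zero", {
  fx <- single_nucleus_fiber(0.03, radius_um = 1.2)
  d <- end_to_nucleus_distance(fx$fiber, fx$nuclei, "dorsal")
  expect_lt(d$distance_um, 0.3)
})

test_that("end and neighbor distances equal exhaustive brute-force oracles", {
  for (s in 1:25) {
    sim <- fixture_fiber(seed = s, um_per_pixel = 0.2)
    fiber <- sim$fiber; nuclei <- sim$nuclei
    for (end in c("dorsal", "ventral")) {
      got <- end_to_nucleus_distance(fiber, nuclei, end)
      oracle <- min(vapply(nuclei$nuclei, function(n)
        oracle_pointset_distance(fiber$end_contours[[end]], n$outline,
                                 fiber$um_per_pixel), numeric(1)))
      expect_equal(got$distance_um, oracle, tolerance = 1e-12)
    }
    nn <- nearest_neighbor_distances(fiber, nuclei)
    oracle_nn <- oracle_nn_distances(nucleus_centroids_px(nuclei),
                                     fiber$um_per_pixel) / fiber$length_um
    expect_equal(nn, oracle_nn, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("evenly spaced nuclei all have the same nearest-neighbor distance", {
  um_per_pixel <- 0.2
  fiber <- make_fiber(40, 6, um_per_pixel)
  n <- 5
  fracs <- seq(0.1, 0.9, length.out = n)
  nuclei <- nucleus_set(lapply(seq_len(n), function(i) {
    ctr <- myoquant:::local_to_px(fiber, fracs[i] * fiber$length_um, 0)
    list(id = i, centroid_px = as.numeric(ctr),
         outline = myoquant:::ellipse_polygon(as.numeric(ctr), 5, 5, fiber$axis),
         area_px = 25 * pi)
  }), um_per_pixel)
  nn <- nearest_neighbor_distances(fiber, nuclei)
  expect_equal(nn, rep(0.8 / (n - 1), n), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(nearest_neighbor_distances(fiber,
                                          nucleus_set(nuclei$nuclei[1],
                                                      um_per_pixel)),
               "undefined")
})

test_that("longest gap matches closed forms and the interval-sweep oracle", {
  # one elliptical nucleus covering [0.4L, 0.6L] axially -> gap 0.4 both sides
  fiber <- make_fiber(40, 6, 0.2)
  ctr <- myoquant:::local_to_px(fiber, 0.5 * fiber$length_um, 0)
  nuc <- nucleus_set(list(list(id = 1L, centroid_px = as.numeric(ctr),
                               outline = myoquant:::ellipse_polygon(
                                 as.numeric(ctr), 4 / 0.2, 2 / 0.2,
                                 fiber$axis, n = 256L),
                               area_px = 10)), 0.2)
  expect_equal(longest_gap(fiber, nuc), 0.4, tolerance = 0.01)
  for (s in 1:25) {
    sim <- fixture_fiber(seed = s, um_per_pixel = 0.2)
    iv <- t(vapply(sim$nuclei$nuclei, function(n) {
      a <- myoquant:::axial_um(sim$fiber, n$outline)
      c(max(0, min(a)), min(sim$fiber$length_um, max(a)))
    }, numeric(2)))
    expect_equal(longest_gap(sim$fiber, sim$nuclei),
                 oracle_longest_gap(iv, sim$fiber$length_um) /
                   sim$fiber$length_um,
                 tolerance = 1e-12)
  }
})

test_that("nuclei tiling the whole axis leave no gap", {
  um_per_pixel <- 0.2
  fiber <- make_fiber(40, 6, um_per_pixel)
  nuclei <- nucleus_set(lapply(1:10, function(i) {
    ctr <- myoquant:::local_to_px(fiber, (i - 0.5) / 10 * fiber$length_um, 0)
    list(id = i, centroid_px = as.numeric(ctr),
         outline = myoquant:::ellipse_polygon(as.numeric(ctr),
                                              2.2 / um_per_pixel, 2,
                                              fiber$axis),
         area_px = 10)
  }), um_per_pixel)
  expect_equal(longest_gap(fiber, nuclei), 0, tolerance = 1e-9)
})

test_that("counting and length report generator truth", {
  sim <- fixture_fiber(seed = 3, um_per_pixel = 0.2)
  expect_equal(count_nuclei(sim$nuclei), 6)
  expect_equal(muscle_length(sim$fiber), 40, tolerance = 0.2 / 40)
  seg <- load_segmentation(sim$image, method = "otsu")
  found <- nuclei_from_labels(seg$nucleus_labels, 0.2)
  expect_equal(count_nuclei(found), 6)
})

test_that("normalized metrics are invariant to pixel size and rotation", {
  ref <- fixture_fiber(seed = 9, um_per_pixel = 0.2)
  metrics <- function(sim) c(
    end_to_nucleus_distance(sim$fiber, sim$nuclei, "dorsal")$normalized,
    end_to_nucleus_distance(sim$fiber, sim$nuclei, "ventral")$normalized,
    mean(nearest_neighbor_distances(sim$fiber, sim$nuclei)),
    longest_gap(sim$fiber, sim$nuclei))
  m0 <- metrics(ref)
  fine <- fixture_fiber(seed = 9, um_per_pixel = 0.1)
  expect_equal(metrics(fine), m0, tolerance = 0.02)
  for (ang in c(20, 45, 75)) {
    rot <- fixture_fiber(seed = 9, um_per_pixel = 0.2, orientation_deg = ang)
    expect_equal(metrics(rot), m0, tolerance = 0.02)
  }
})

test_that("square masks trigger the degenerate-axis warning", {
  m <- matrix(TRUE, 20, 20)
  expect_warning(fiber_from_mask(m, 0.2), "close to its width")
})
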