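presets <- default_genotype_presets()

test_that("identity and doubled channels give flat 100 and 200 profiles", {
  sim <- fixture_fiber(seed = 1)
  img <- sim$image
  img$channels$target <- img$channels$reference
  roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
  raw <- compute_ratio_profile(img, roi, mask = sim$fiber$mask)
  expect_equal(raw$data$ratio, rep(100, nrow(raw$data)), tolerance = 1e-9)
  img$channels$target <- 2 * img$channels$reference
  raw2 <- compute_ratio_profile(img, roi, mask = sim$fiber$mask)
  expect_equal(raw2$data$ratio, rep(200, nrow(raw2$data)), tolerance = 1e-9)
})

test_that("profile ROIs stay inside the mask across random fibers", {
  for (s in 1:50) {
    sim <- fixture_fiber(seed = s, um_per_pixel = 0.2,
                         orientation_deg = (s * 37) %% 90)
    for (end in c("dorsal", "ventral")) {
      roi <- suppressWarnings(select_profile_roi(sim$fiber, sim$nuclei, end))
      pts <- myoquant:::roi_sample_points(roi)
      inside <- sim$fiber$mask[cbind(round(pts[, "y"]) + 1,
                                     round(pts[, "x"]) + 1)]
      expect_true(all(inside), label = sprintf("seed %d %s", s, end))
    }
  }
})

test_that("the ROI pixel set is identical across channels by construction", {
  sim <- fixture_fiber(seed = 4)
  roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
  raw_t <- compute_ratio_profile(sim$image, roi, mask = sim$fiber$mask)
  raw_n <- compute_ratio_profile(sim$image, roi,
                                 channels = c(target = "nuclei",
                                              reference = "reference"),
                                 mask = sim$fiber$mask)
  expect_identical(raw_t$data$position_px, raw_n$data$position_px)
  expect_identical(raw_t$data$n_pixels, raw_n$data$n_pixels)
})

test_that("noiseless measured profiles match the analytic truth curve", {
  for (s in 1:10) {
    for (geno in c("control", "syd_like")) {
      sim <- fixture_fiber(preset = presets[[geno]], seed = s)
      tf <- truth_ratio_fun(presets[[geno]])
      roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
      prof <- normalize_profile(compute_ratio_profile(sim$image, roi,
                                                      mask = sim$fiber$mask))
      err <- max(abs(prof$ratio - tf(prof$positions)))
      expect_lt(err, 0.02 * max(tf(seq(0, 100, 1))))
    }
  }
})

test_that("constant and linear profiles give closed-form peak and AUC", {
  pos <- seq(0, 12, by = 0.5)
  const <- normalize_profile(data.frame(position_um = pos,
                                        ratio = rep(7, length(pos))))
  expect_equal(const$peak, 7)
  expect_equal(const$auc, 700)
  ramp <- normalize_profile(data.frame(position_um = pos,
                                       ratio = 3 * pos / max(pos)))
  expect_equal(ramp$peak, 3)
  expect_equal(ramp$auc, 150)   # trapezoid exact for a linear ramp
  expect_error(normalize_profile(data.frame(position_um = 1:3, ratio = 1:3)),
               "4 raw positions")
})

test_that("normalized AUC agrees with a 10x-oversampled numeric integral", {
  withr::with_seed(11, {
    for (i in 1:5) {
      pos <- seq(0, 10, length.out = 40)
      vals <- 50 + cumsum(rnorm(40))
      prof <- normalize_profile(data.frame(position_um = pos, ratio = vals))
      fine <- seq(0, 100, length.out = 1001)
      pct <- (pos - min(pos)) / diff(range(pos)) * 100
      oracle <- pracma::trapz(fine, approx(pct, vals, xout = fine)$y)
      expect_equal(prof$auc, oracle, tolerance = 0.01)
    }
  })
})

test_that("profiles are invariant to joint channel scaling and fiber stretch", {
  sim <- fixture_fiber(seed = 6)
  roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
  base <- compute_ratio_profile(sim$image, roi, mask = sim$fiber$mask)
  scaled <- sim$image
  scaled$channels$target <- scaled$channels$target * 3.7
  scaled$channels$reference <- scaled$channels$reference * 3.7
  expect_equal(compute_ratio_profile(scaled, roi,
                                     mask = sim$fiber$mask)$data$ratio,
               base$data$ratio, tolerance = 1e-9)
  # stretching the fiber (and nucleus positions with it) leaves the
  # normalized profile unchanged within interpolation error
  p <- noiseless(presets$control)
  long <- simulate_fiber(p, length_um = 80, width_um = 6, um_per_pixel = 0.1,
                         seed = 6)
  prof_short <- normalize_profile(base)
  roi_l <- select_profile_roi(long$fiber, long$nuclei, "dorsal")
  prof_long <- normalize_profile(compute_ratio_profile(long$image, roi_l,
                                                       mask = long$fiber$mask))
  tf <- truth_ratio_fun(p)
  peak <- max(tf(seq(0, 100, 1)))
  expect_lt(max(abs(prof_short$ratio - prof_long$ratio)), 0.04 * peak)
})

test_that("peak >= auc/100 >= minimum for measured profiles", {
  for (s in 1:5) {
    sim <- fixture_fiber(seed = s, noise = TRUE)
    roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
    prof <- normalize_profile(compute_ratio_profile(sim$image, roi,
                                                    mask = sim$fiber$mask))
    expect_gte(prof$peak, prof$auc / 100)
    expect_gte(prof$auc / 100, min(prof$ratio))
  }
})

test_that("fixed-box profile has closed-form AUC and finds the nucleus-edge peak", {
  sim <- fixture_fiber(seed = 2)
  img <- sim$image
  img$channels$target <- img$channels$reference   # flat 100
  fb <- fixed_box_profile(img, sim$fiber, sim$nuclei, box_length_um = 2)
  expect_equal(attr(fb, "auc"), 2 * 100, tolerance = 1e-6)
  # nucleus-enriched target peaks within 1 um of the nucleus edge
  simn <- fixture_fiber(preset = presets$syd_like, seed = 2)
  fbn <- fixed_box_profile(simn$image, simn$fiber, simn$nuclei,
                           box_length_um = 5)
  peak_pos <- fbn$data$position_um[which.max(fbn$data$ratio)]
  expect_lt(peak_pos, 1)
  expect_error(fixed_box_profile(simn$image, simn$fiber, simn$nuclei,
                                 box_length_um = 50), "exceeds")
})

test_that("distal ratio behaves as a local end statistic", {
  sim <- fixture_fiber(seed = 3)
  img <- sim$image
  img$channels$target <- img$channels$reference
  expect_equal(distal_region_ratio(img, sim$fiber), 100, tolerance = 1e-9)
  img$channels$target[] <- 0
  expect_equal(distal_region_ratio(img, sim$fiber), 0)
  # end-enriched target: distal ratio exceeds the whole-fiber ratio
  whole_ratio <- 100 * mean(sim$image$channels$target[sim$fiber$mask]) /
    mean(sim$image$channels$reference[sim$fiber$mask])
  expect_gt(distal_region_ratio(sim$image, sim$fiber), whole_ratio)
})

test_that("cohort averaging follows the closed forms", {
  sim <- fixture_fiber(seed = 5)
  roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
  prof <- normalize_profile(compute_ratio_profile(sim$image, roi,
                                                  mask = sim$fiber$mask))
  avg2 <- average_profiles(list(prof, prof))
  expect_equal(avg2$mean, prof$ratio)
  expect_equal(max(avg2$sd), 0)
  p3 <- prof; p3$ratio <- 3 * prof$ratio
  p3$peak <- 3 * prof$peak; p3$auc <- 3 * prof$auc
  avg <- average_profiles(list(prof, p3))
  expect_equal(avg$mean, 2 * prof$ratio)
  expect_equal(avg$sd, sqrt(2) * prof$ratio, tolerance = 1e-9)
  expect_equal(avg$peak_mean, 2 * prof$peak)
  bad <- prof; bad$positions <- seq(0, 100, length.out = 51)
  bad$ratio <- bad$ratio[1:51]
  expect_error(average_profiles(list(prof, bad)), "mismatched grids")
})

test_that("reference control check flags only true reference differences", {
  make_raws <- function(preset, n, seed0) lapply(seq_len(n), function(i) {
    sim <- fixture_fiber(preset = preset, seed = seed0 + i, noise = TRUE)
    roi <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal")
    compute_ratio_profile(sim$image, roi, mask = sim$fiber$mask)
  })
  same <- make_raws(presets$control, 8, 100)
  same2 <- make_raws(presets$syd_like, 8, 200)
  bright <- presets$syd_like
  bright$reference_level <- 2 * bright$reference_level
  doubled <- make_raws(bright, 8, 300)
  tab <- reference_control_check(list(control = same, mutant = doubled))
  expect_true(tab$flagged[tab$genotype == "mutant"])
  expect_error(reference_control_check(list(control = same)), "2 genotypes")
  tab2 <- reference_control_check(list(control = same, other = same2))
  expect_false(tab2$flagged[tab2$genotype == "other"])
})
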