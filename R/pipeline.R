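#' Experiment configuration
#'
#' Assembles and validates the configuration of a full experiment run:
#' which genotype presets to simulate (or which user files to analyze), the
#' cohort design, and every analysis parameter that the measurement
#' protocol leaves open, each with its documented default.
#'
#' The default cohort design mirrors the embryonic assay structure: all
#' four lateral-transverse muscles in three hemisegments of ten embryos per
#' genotype for positioning metrics, and two muscles per hemisegment for
#' intensity profiles.
#'
#' @param genotypes character vector of preset names; the first is the
#'   control.
#' @param presets named list of [genotype_preset()] objects (defaults to
#'   the shipped library).
#' @param cohort list: `muscles_per_hemisegment`, `hemisegments_per_embryo`,
#'   `embryos`.
#' @param profile_cohort same shape, for intensity profiles.
#' @param fiber list: `length_um`, `width_um`, `um_per_pixel`,
#'   `orientation_deg`.
#' @param analysis list: `box_width_um`, `grid_points`, `distal_depth_um`,
#'   `profile_end`, `alpha_levels`.
#' @param seed integer; every random draw in the run derives from it (no
#'   silent clock seeding).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(genotypes = c("control", "syd_like"),
                              presets = NULL,
                              cohort = list(muscles_per_hemisegment = 4,
                                            hemisegments_per_embryo = 3,
                                            embryos = 10),
                              profile_cohort = list(muscles_per_hemisegment = 2,
                                                    hemisegments_per_embryo = 3,
                                                    embryos = 10),
                              fiber = list(length_um = 40, width_um = 6,
                                           um_per_pixel = 0.1,
                                           orientation_deg = 0),
                              analysis = list(box_width_um = 2,
                                              grid_points = 101L,
                                              distal_depth_um = 2,
                                              profile_end = "dorsal",
                                              alpha_levels = c(0.05, 0.01)),
                              seed = 1L) {
  presets <- presets %||% default_genotype_presets()
  missing_p <- setdiff(genotypes, names(presets))
  if (length(missing_p))
    stop("no preset defined for genotype(s): ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  if (is.null(seed)) stop("an explicit seed is required", call. = FALSE)
  structure(list(genotypes = genotypes, presets = presets[genotypes],
                 control = genotypes[1], cohort = cohort,
                 profile_cohort = profile_cohort, fiber = fiber,
                 analysis = analysis, seed = as.integer(seed)),
            class = "experiment_config")
}

cohort_size <- function(ch) ch$muscles_per_hemisegment *
  ch$hemisegments_per_embryo * ch$embryos

#' Run a full synthetic experiment
#'
#' Generates per-genotype cohorts of synthetic fibers, measures nuclear
#' positioning on the full positioning cohort and ratio profiles (peak,
#' AUC, distal ratio, reference totals) on the profile cohort, and builds
#' the dual-significance statistical report against the control genotype.
#' With an output directory, tidy CSVs and a JSON manifest are written;
#' outputs are byte-identical across runs with the same configuration and
#' seed.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return List with `measurements`, `profile_stats`, `cohort_curves`,
#'   `reference_check`, `report`, `manifest`, `errors`.
#' @export
run_synthetic_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  n_pos <- cohort_size(config$cohort)
  n_prof <- cohort_size(config$profile_cohort)
  fib <- config$fiber
  an <- config$analysis
  measurements <- NULL
  profile_stats <- NULL
  cohort_curves <- list()
  raw_by_geno <- list()
  errors <- NULL
  withr::with_seed(config$seed, {
    for (g in config$genotypes) {
      preset <- config$presets[[g]]
      profs <- list()
      raws <- list()
      for (i in seq_len(max(n_pos, n_prof))) {
        res <- tryCatch({
          fiber <- make_fiber(fib$length_um, fib$width_um, fib$um_per_pixel,
                              fib$orientation_deg)
          nuclei <- place_nuclei(fiber, preset)
          out <- list()
          if (i <= n_pos) {
            pr <- position_report(fiber, nuclei,
                                  fiber_id = sprintf("%s_%03d", g, i))
            pr$genotype <- g
            out$pos <- pr
          }
          if (i <= n_prof) {
            rc <- render_channels(fiber, nuclei, preset)
            roi <- select_profile_roi(fiber, nuclei, an$profile_end,
                                      width_um = an$box_width_um)
            raw <- compute_ratio_profile(rc$image, roi, mask = fiber$mask)
            prof <- normalize_profile(raw, grid_points = an$grid_points)
            dr <- distal_region_ratio(rc$image, fiber,
                                      depth_um = an$distal_depth_um,
                                      end = an$profile_end)
            out$prof <- prof
            out$raw <- raw
            out$prof_row <- data.frame(
              genotype = g, fiber_id = sprintf("%s_%03d", g, i),
              peak = prof$peak, auc = prof$auc, span_um = prof$span_um,
              distal_ratio = dr, reference_total = reference_total(raw))
          }
          out
        }, error = function(e) e)
        if (inherits(res, "error")) {
          errors <- rbind(errors, data.frame(genotype = g, fiber = i,
                                             message = conditionMessage(res)))
          next
        }
        if (!is.null(res$pos)) measurements <- rbind(measurements, res$pos)
        if (!is.null(res$prof)) {
          profs[[length(profs) + 1]] <- res$prof
          raws[[length(raws) + 1]] <- res$raw
          profile_stats <- rbind(profile_stats, res$prof_row)
        }
      }
      if (length(profs) >= 2) cohort_curves[[g]] <- average_profiles(profs)
      raw_by_geno[[g]] <- raws
    }
  })
  # statistical report: positioning metrics + profile statistics
  stat_input <- rbind(
    measurements[, c("genotype", "fiber_id", "metric", "value")],
    if (!is.null(profile_stats)) do.call(rbind, lapply(
      c("peak", "auc", "distal_ratio"), function(m)
        data.frame(genotype = profile_stats$genotype,
                   fiber_id = profile_stats$fiber_id,
                   metric = m, value = profile_stats[[m]])))
  )
  report <- build_report(stat_input, control = config$control)
  ref_check <- if (length(raw_by_geno) >= 2)
    reference_control_check(raw_by_geno, control = config$control) else NULL
  manifest <- list(package = "myoquant",
                   version = as.character(utils::packageVersion("myoquant")),
                   seed = config$seed,
                   genotypes = config$genotypes,
                   cohort = config$cohort,
                   profile_cohort = config$profile_cohort,
                   fiber = config$fiber,
                   analysis = config$analysis)
  bundle <- list(measurements = measurements, profile_stats = profile_stats,
                 cohort_curves = cohort_curves, reference_check = ref_check,
                 report = report, manifest = manifest, errors = errors)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  if (!is.null(errors))
    warning(sprintf("%d fiber(s) failed; see $errors", nrow(errors)),
            call. = FALSE)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) if (!is.null(df))
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(bundle$measurements, "measurements.csv")
  wcsv(bundle$profile_stats, "profile_stats.csv")
  wcsv(bundle$report$descriptives, "descriptives.csv")
  wcsv(bundle$report$comparisons, "comparisons.csv")
  wcsv(bundle$reference_check, "reference_check.csv")
  if (length(bundle$cohort_curves)) {
    curves <- do.call(rbind, lapply(names(bundle$cohort_curves), function(g) {
      cc <- bundle$cohort_curves[[g]]
      data.frame(genotype = g, position_pct = cc$positions,
                 ratio_mean = cc$mean, ratio_sd = cc$sd)
    }))
    wcsv(curves, "cohort_curves.csv")
  }
  wcsv(bundle$errors, "errors.csv")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Analyze user-supplied images
#'
#' Runs the same measurements as [run_synthetic_experiment()] on images on
#' disk: each image is read, segmented (automatically or from provided
#' masks), converted to fiber geometry and nuclei, and measured. Images
#' with differing calibrations are analyzed with their own pixel size and
#' a consistency warning is raised.
#'
#' @param files data.frame with columns `path`, `genotype` and optionally
#'   `mask_path` (label TIFF: page 1 fiber mask, page 2 nucleus labels).
#' @param config an [experiment_config()] supplying analysis parameters.
#' @param channel_map passed to [read_image()] when a file has no sidecar.
#' @param profiles also compute ratio profiles (needs reference/target
#'   channels).
#' @param out_dir optional output directory.
#' @return Bundle as in [run_synthetic_experiment()].
#' @export
run_user_data <- function(files, config = experiment_config(),
                          channel_map = NULL, profiles = TRUE,
                          out_dir = NULL) {
  need <- c("path", "genotype")
  if (!all(need %in% names(files)))
    stop("files needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  an <- config$analysis
  measurements <- NULL; profile_stats <- NULL; errors <- NULL
  upps <- numeric(0)
  raw_by_geno <- list()
  for (i in seq_len(nrow(files))) {
    res <- tryCatch({
      img <- read_image(files$path[i], channel_map = channel_map)
      upps <- c(upps, img$um_per_pixel)
      seg <- if (!is.null(files$mask_path) && !is.na(files$mask_path[i])) {
        masks <- read_image(files$mask_path[i])
        load_segmentation(list(fiber_mask = masks$channels[[1]],
                               nucleus_labels = round(masks$channels[[2]])),
                          method = "provided")
      } else load_segmentation(img, method = "otsu")
      fiber <- fiber_from_mask(seg$fiber_mask, img$um_per_pixel)
      nuclei <- nuclei_from_labels(seg$nucleus_labels, img$um_per_pixel)
      fid <- sprintf("%s_%03d", files$genotype[i], i)
      pr <- position_report(fiber, nuclei, fiber_id = fid)
      pr$genotype <- files$genotype[i]
      out <- list(pos = pr)
      if (profiles) {
        roi <- select_profile_roi(fiber, nuclei, an$profile_end,
                                  width_um = an$box_width_um)
        raw <- compute_ratio_profile(img, roi, mask = fiber$mask)
        prof <- normalize_profile(raw, grid_points = an$grid_points)
        dr <- distal_region_ratio(img, fiber, depth_um = an$distal_depth_um,
                                  end = an$profile_end)
        out$raw <- raw
        out$prof_row <- data.frame(genotype = files$genotype[i], fiber_id = fid,
                                   peak = prof$peak, auc = prof$auc,
                                   span_um = prof$span_um, distal_ratio = dr,
                                   reference_total = reference_total(raw))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(path = files$path[i],
                                         message = conditionMessage(res)))
      next
    }
    measurements <- rbind(measurements, res$pos)
    if (!is.null(res$prof_row)) {
      profile_stats <- rbind(profile_stats, res$prof_row)
      g <- files$genotype[i]
      raw_by_geno[[g]] <- c(raw_by_geno[[g]], list(res$raw))
    }
  }
  if (length(unique(round(upps, 10))) > 1)
    warning("mixed pixel calibrations across files; per-file um/px used",
            call. = FALSE)
  if (is.null(measurements)) stop("no file could be analyzed", call. = FALSE)
  stat_input <- measurements[, c("genotype", "fiber_id", "metric", "value")]
  if (!is.null(profile_stats))
    stat_input <- rbind(stat_input, do.call(rbind, lapply(
      c("peak", "auc", "distal_ratio"), function(m)
        data.frame(genotype = profile_stats$genotype,
                   fiber_id = profile_stats$fiber_id,
                   metric = m, value = profile_stats[[m]]))))
  report <- build_report(stat_input, control = config$control)
  bundle <- list(measurements = measurements, profile_stats = profile_stats,
                 cohort_curves = list(),
                 reference_check = if (length(raw_by_geno) >= 2 &&
                                       all(lengths(raw_by_geno) >= 2))
                   reference_control_check(raw_by_geno,
                                           control = config$control) else NULL,
                 report = report,
                 manifest = list(package = "myoquant",
                                 version = as.character(utils::packageVersion("myoquant")),
                                 mode = "user_data", n_files = nrow(files)),
                 errors = errors)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}
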