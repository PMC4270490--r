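#' Genotype presets for the synthetic generator
#'
#' A preset bundles the nucleus-placement model, the target-channel intensity
#' model, the reference-channel level, and the noise model for one simulated
#' genotype/condition. Presets ship as data (a YAML file under
#' `inst/extdata/genotype_presets.yaml`) so users can add genotypes without
#' touching code.
#'
#' The target model describes the ratio-forming channel along each
#' end-to-nearest-nucleus span: intensity at fractional span position x (0 =
#' muscle end, 1 = nucleus edge) is
#' `baseline + peak_amplitude * exp(-|x - peak_position| / decay_length)`,
#' blended with a diffuse component `baseline + peak_amplitude / 2` with
#' weight `mixture_weight_diffuse`. `peak_position = 0` is end-enriched
#' (control-like cortical motor accumulation), `peak_position = 1` is
#' nucleus-enriched (mutant-like), and a high diffuse weight gives a mixed,
#' spread-out distribution.
#'
#' @param name label for the genotype.
#' @param nucleus_placement list with `cluster_centers` (fractional axial
#'   positions in \[0, 1\]), `cluster_sd` (fraction), `n_nuclei` (count).
#' @param target_model list with `baseline`, `peak_amplitude` (a.u.),
#'   `peak_position`, `decay_length`, `mixture_weight_diffuse` (all
#'   fractions in \[0, 1\] except the two intensities).
#' @param reference_level reference-channel intensity inside the fiber (a.u.).
#' @param noise list with `gaussian_sd` (a.u.) and `poisson_like` flag; when
#'   `poisson_like` is `TRUE` the per-pixel noise SD grows with the square
#'   root of the signal.
#' @param nucleus_shape list with `semi_major_um`, `semi_minor_um` of the
#'   elliptical nuclei.
#' @return A validated object of class `genotype_preset`.
#' @export
genotype_preset <- function(name,
                            nucleus_placement,
                            target_model,
                            reference_level,
                            noise = list(gaussian_sd = 0, poisson_like = FALSE),
                            nucleus_shape = list(semi_major_um = 1.4,
                                                 semi_minor_um = 1.0)) {
  np <- nucleus_placement; tm <- target_model
  frac_ok <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1)
  if (!frac_ok(np$cluster_centers) || !frac_ok(np$cluster_sd))
    stop("cluster centers and sd must be fractions in [0, 1]", call. = FALSE)
  if (is.null(np$n_nuclei) || np$n_nuclei < 1)
    stop("n_nuclei must be >= 1", call. = FALSE)
  if (!frac_ok(tm$peak_position) || !frac_ok(tm$mixture_weight_diffuse))
    stop("peak_position and mixture_weight_diffuse must be in [0, 1]", call. = FALSE)
  if (tm$decay_length <= 0 || tm$decay_length > 1)
    stop("decay_length must be in (0, 1]", call. = FALSE)
  if (tm$baseline < 0 || tm$peak_amplitude < 0 || reference_level <= 0)
    stop("intensities must be nonnegative and reference_level positive", call. = FALSE)
  if (noise$gaussian_sd < 0) stop("gaussian_sd must be >= 0", call. = FALSE)
  structure(list(name = name,
                 nucleus_placement = np,
                 target_model = tm,
                 reference_level = reference_level,
                 noise = noise,
                 nucleus_shape = nucleus_shape),
            class = "genotype_preset")
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf("<genotype_preset> %s: %d nuclei at (%s), target peak at %.0f%% of span\n",
              x$name, x$nucleus_placement$n_nuclei,
              paste(x$nucleus_placement$cluster_centers, collapse = ", "),
              100 * x$target_model$peak_position))
  invisible(x)
}

#' Load genotype presets from a YAML file
#'
#' @param path YAML file; defaults to the preset library shipped with the
#'   package (control, syd-like, khc-like, bsk-dn-like, hep-act-like).
#' @return Named list of [genotype_preset()] objects.
#' @export
load_genotype_presets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "genotype_presets.yaml",
                                package = "myoquant", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    genotype_preset(name = nm,
                    nucleus_placement = p$nucleus_placement,
                    target_model = p$target_model,
                    reference_level = p$reference_level,
                    noise = p$noise %||% list(gaussian_sd = 0, poisson_like = FALSE),
                    nucleus_shape = p$nucleus_shape %||%
                      list(semi_major_um = 1.4, semi_minor_um = 1.0))
  })
  names(out) <- names(raw)
  out
}

#' Default genotype presets
#'
#' Convenience wrapper around [load_genotype_presets()] for the shipped
#' preset library.
#' @return Named list of [genotype_preset()] objects.
#' @export
default_genotype_presets <- function() load_genotype_presets()
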