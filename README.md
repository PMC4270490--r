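# myoquant

Quantification of myonuclear positioning, motor-protein localization,
nuclear dynamics, and muscle function in *Drosophila* muscle images.

Syncytial muscle fibers normally spread their nuclei into a stereotyped
pattern — two end clusters in embryonic lateral-transverse muscles, even
spacing in larval ventral-longitudinal muscles. Microtubule motors
(Kinesin, Dynein) and their adaptors position those nuclei, in part by
Dynein-mediated cortical pulling from the muscle ends; mutants leave
nuclei clumped mid-fiber and shift the motors' spatial distribution
toward the nucleus. `myoquant` is the measurement pipeline for this
biology, for imaging labs and method developers who need the published
quantification scheme as reusable, tested code.

## What it computes

* **Positioning** — shortest end-to-nucleus distance (boundary to
  boundary), nearest-neighbor spacing, longest nucleus-free gap, nucleus
  counts, muscle length; all normalized to muscle length.
* **Localization profiles** — target/reference intensity ratio `r(x) =
  100 · I_target(x) / I_ref(x)`, averaged across a box of set width along
  the span from a muscle end to the nearest nucleus, resampled to a
  normalized position axis (0% = muscle end, 100% = nucleus); summarized
  by the peak `max r` and the total fluorescence `AUC = ∫ r dx`
  (trapezoid). Fixed-dimension box and distal-2 µm variants included.
* **Nuclear dynamics** — aspect-ratio extremes from polygon second
  moments, shape changes per hour via a hysteresis classifier, percentage
  of direction-changing nuclei, kymographs.
* **Locomotion & viability** — crawl velocity (path length / time) and
  stage-survival percentages normalized to embryo counts.
* **Statistics** — mean ± SD, and the dual-significance rule: a
  comparison is significant only if the pairwise Student's *t*-test
  **and** the omnibus one-way ANOVA both pass (`*` p < 0.05, `**`
  p < 0.01).
* **Synthetic data** — a generator for fiber images, nucleus placements,
  nucleus tracks, and larval tracks under named genotype presets, with
  analytic ground-truth ratio curves, so the whole pipeline is verifiable
  without raw microscopy.

## Worked example

```r
library(myoquant)

presets <- default_genotype_presets()
sim <- simulate_fiber(presets$control, seed = 42)   # fiber + nuclei + image
sim$fiber
#> <fiber_geometry> 40.0 um x 6.0 um, 0.2 um/px, axis (1.000, 0.000)

d <- end_to_nucleus_distance(sim$fiber, sim$nuclei, "dorsal")
sprintf("dorsal end-to-nucleus: %.3f (normalized), %.2f um", d$normalized, d$distance_um)
#> "dorsal end-to-nucleus: 0.056 (normalized), 2.23 um"

longest_gap(sim$fiber, sim$nuclei)
#> 0.475

roi  <- select_profile_roi(sim$fiber, sim$nuclei, "dorsal", width_um = 2)
prof <- normalize_profile(compute_ratio_profile(sim$image, roi, mask = sim$fiber$mask))
prof
#> <localization_profile> span 2.23 um, peak 121.1, AUC 7398

distal_region_ratio(sim$image, sim$fiber, depth_um = 2)
#> 77.8
```

The control nuclei sit ~2 µm from the dorsal end (0.056 of muscle
length); the largest nucleus-free stretch is mid-fiber (0.475 of the
length, between the two end clusters). The ratio profile peaks at the
muscle end (121 vs a far-end baseline near 54), as expected for an
end-enriched motor in a control fiber, and the distal 2 µm ratio (77.8)
sits well above the fiber-wide mean.

A full experiment — cohorts per genotype, profile statistics, and the
dual-significance report against the control — is one call:

```r
cfg <- experiment_config(genotypes = c("control", "syd_like"), seed = 1)
bundle <- run_synthetic_experiment(cfg, out_dir = "results/")
bundle$report$comparisons     # per-metric p_t, p_anova, stars
```

For images on disk, `run_user_data()` takes a table of paths (TIFF, one
page per channel; masks optional) and produces the same bundle. A thin
CLI with `simulate`, `positions`, `profiles`, `dynamics`, `locomotion`,
`viability`, `stats` and `run-all` subcommands is installed at
`system.file("cli", "myoquant", package = "myoquant")`.

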