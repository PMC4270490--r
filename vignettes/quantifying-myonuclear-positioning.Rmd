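---
title: "Quantifying myonuclear positioning and motor protein localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myonuclear positioning and motor protein localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

## The measurement problem

Body-wall muscles of *Drosophila* embryos and larvae are syncytial fibers
whose nuclei normally spread into a stereotyped pattern: in embryonic
lateral-transverse (LT) muscles the myonuclei form two groups near the
dorsal and ventral fiber ends, and in larval ventral-longitudinal (VL)
muscles they space out evenly along the fiber. Mutations in the
microtubule-motor machinery (Kinesin, Dynein, and adaptor proteins that
couple them, with JNK-pathway input) leave nuclei clumped in mid-fiber.
The same machinery localizes differently along the fiber: in controls,
Dynein accumulates at the muscle ends where it pulls microtubules — and the
attached nuclei — toward the cortex ("cortical pulling"), while in adaptor
mutants the motors pile up near the nuclei instead.

`myoquant` implements the quantification side of this biology as a
reusable, tested pipeline:

* **positioning metrics** — shortest end-to-nucleus distance,
  nearest-neighbor spacing, longest nucleus-free gap, nucleus count, and
  muscle length, all normalized to muscle length;
* **localization profiles** — target/reference intensity ratio (x 100)
  along the span from a muscle end to the nearest nucleus, resampled to a
  normalized 0–100 position axis, summarized by peak and area under the
  curve (AUC, "total fluorescence"), with fixed-box and distal-zone
  variants;
* **nuclear dynamics** — aspect-ratio extremes, shape changes per hour,
  direction-change percentages, and kymographs from time-lapse tracks;
* **locomotion and viability** — crawl velocity from centroid tracks and
  stage-survival percentages;
* **statistics** — mean/SD descriptives and a dual-significance rule
  (pairwise Student's *t* **and** omnibus one-way ANOVA must both pass);
* **a synthetic-data generator** with analytic ground truth, so every stage
  above is verifiable end to end without raw microscopy.

## The intensity model and its ground truth

A structural stain (Tropomyosin) serves as the reference channel: it is
spatially uniform in healthy fibers and similar across genotypes, which is
what makes the target/reference ratio comparable between images. The
generator renders the reference channel at a constant level inside the
fiber mask, and the target channel along each end-to-nearest-nucleus span
of length $S$ as

$$I(x) = (1 - w)\left[b + A\,e^{-|x - p|/\lambda}\right] + w\left[b + A/2\right],
\qquad x \in [0, 1],$$

where $x$ is position along the span as a fraction (0 = muscle end, 1 =
nucleus edge), $b$ is the baseline, $A$ the peak amplitude, $p$ the peak
position, $\lambda$ the decay length (all fractions of the span), and $w$
a diffuse-mixture weight. Because $x$ and $\lambda$ are span-relative, the
analytic ratio curve $100\,I(x)/\mathrm{ref}$ is independent of the span
length — so a genotype that *shifts* its nuclei (changing $S$) but not its
motor distribution has exactly the same truth curve and truth AUC as the
control. That property mirrors the biological contrast the AUC statistic
is designed to capture: a *redistribution* of motor protein (distal ratio
falls, AUC unchanged) versus a *loss* (AUC falls).

Two rasterization choices matter when comparing measurement to truth:

* span position 0 is anchored at the **terminal pixel center**, not the
  physical fiber edge half a pixel further out, because that is where a
  measurement box can anchor;
* the model is clamped to $x \in [0, 1]$, so pixels beyond the span carry
  the at-nucleus value and the field is continuous.

Noise is additive Gaussian (SD in arbitrary units) with an optional
Poisson-like term that scales the per-pixel SD with $\sqrt{\text{signal}}$;
values are clipped at zero. Fluorescence noise is not literally Gaussian,
but nothing in the measured statistics depends on higher moments.

## Genotype presets

Presets ship as data (`inst/extdata/genotype_presets.yaml`) rather than
code. The published source for these phenotypes reports bar charts from
undeposited microscopy, so presets are calibrated to reproduce the
*ordering* of phenotypes, not absolute values:

| preset | nuclei | target distribution |
|---|---|---|
| `control` | clusters at 0.10/0.90 of the axis | end-enriched ($p = 0$) |
| `syd_like` | clumped mid-fiber (0.35/0.65) | nucleus-enriched ($p = 1$) |
| `khc_like` | clumped (0.30/0.70) | nucleus-enriched |
| `bsk_dn_like` | clumped, broader | nucleus-enriched, more diffuse |
| `hep_act_like` | three loose clusters | mixed/diffuse ($w = 0.6$) |

Shared numbers, chosen once as plausible for this imaging regime: fiber
40 x 6 µm (LT-muscle scale), 0.1 µm/px (high-magnification confocal
sampling), 6 nuclei of 1.4 x 1.0 µm semi-axes per fiber, reference level
200 a.u., baseline 100, amplitude 150, decay length 0.3, Gaussian SD 6
with the Poisson-like term on. Nuclei keep a 2 µm standoff from the fiber
ends (`end_clearance_um`), which both reflects the visible bracket
distances in control muscles and keeps the end-to-nucleus span a
measurable, strictly positive quantity; the decay length is deliberately
no steeper than a few pixels at the default calibration, since a
sub-resolution exponential cannot be measured faithfully by any box
profile. What the generator does **not** emulate: optics (PSF, bleed-
through, depth attenuation), sarcomere texture, curved or tapered fibers,
3-D nuclear overlap. Tests passing on synthetic data therefore validate
the *measurement* code, not robustness to those real-world effects; the
manual-mask path exists precisely so users can bypass the bundled
segmentation when images get hard.

## Measurement conventions and open choices

Where the published protocol is ambiguous, the package picks one reading,
documents it, and (where reasonable) exposes the alternative:

* **End-to-nucleus distance** is boundary-to-boundary Euclidean (end
  contour to nucleus outline), not centroid- or axis-projected — matching
  how the bracket is drawn between muscle end and nucleus body.
  Normalization is by the axial extent of the mask ("muscle length"); the
  dorsoventral midline arc is the uncomputed alternative.
* **Nearest-neighbor spacing** uses centroids: the stable estimator of
  nucleus *position* when outlines touch.
* **Longest gap** counts the fiber ends as gap boundaries, so a
  nucleus-free muscle end scores as a gap.
* **Profile box width** is never stated in the protocol ("a box of set
  width"); the default is 2 µm, configurable. If the box would leave the
  fiber mask it is narrowed with a warning, never silently.
* **Peak intensity** is the maximum of the width-averaged ratio curve.
  The protocol's "greatest pixel intensity" could also mean unaveraged
  pixels; the averaged reading is less noise-inflated and is what the
  curve itself displays.
* **Normalized resampling** uses a 101-point grid (1% steps) and linear
  interpolation; AUC is trapezoidal. Cohort peak/AUC statistics are means
  of per-profile values, not statistics of the mean curve; the curves are
  averaged as mean-of-normalized-profiles (the alternative,
  normalize-the-mean, is not computed).
* **Shape-change counting** classifies spherical vs elongated with
  hysteresis (enter elongated at aspect ratio >= 1.4, return at <= 1.2;
  both configurable). The published definition is pictorial; hysteresis
  makes the event count invariant to oversampling and robust to outline
  noise.
* **Direction change "per hour"** is read as the fraction of nuclei with
  at least one reversal, each track's indicator divided by its duration in
  hours; a displacement below 0.5 µm (configurable) within the sliding
  window counts as jitter, not motion.
* **Crawl velocity** is path length over elapsed time; a net-displacement
  variant is available by flag since the original tracking method is
  specified only by citation.
* **Dual significance**: a comparison is starred only when the pairwise
  pooled-variance *t*-test *and* the omnibus one-way ANOVA both clear the
  threshold (`*` 0.05, `**` 0.01). The ANOVA is the omnibus test, not a
  contrast. Welch's correction is available by flag but off by default
  ("Student's t-test"). No multiple-testing correction is applied (none
  was in the source protocol); reports carry the comparison count so users
  can add their own. Each muscle measurement is one observation —
  embryo/hemisegment nesting is deliberately not modeled.

## Numerical choices

* Coordinates are 0-based pixel-centered, row-major, y down; physical
  units are µm via `um_per_pixel`. Muscle length is the projected pixel
  extent plus one pixel, so an axis-aligned 200-pixel fiber at 0.2 µm/px
  reports exactly 40 µm.
* Profile sampling is bilinear, restricted to the fiber mask (weights
  renormalized at the boundary) so background zeros never dilute the
  reference denominator; a zero-mean reference at any position is an
  error, not a silent NaN.
* Nucleus placement is rejection sampling in fiber-local coordinates
  (identical physical placements for any raster orientation or pixel
  size), with a Minkowski-style ellipse-contact test plus a 0.4 µm gap so
  segmentation can separate neighbors; the greedy fill restarts up to 20
  times before declaring the density infeasible.
* Degenerate statistics are defined, not NaN: zero pooled variance gives
  p = 1 (equal means) or p = 0 with a warning (unequal); SD is reported
  absent at n = 1; one nucleus makes nearest-neighbor spacing an error
  ("undefined"), not zero.
* All randomness flows through explicit seeds (`withr::with_seed`), and a
  full experiment writes byte-identical CSVs for identical
  (configuration, seed).

## Verification strategy and problem sizes

The test suite checks every geometric statistic against independently
coded brute-force oracles (exhaustive pairwise distances, interval sweeps,
PCA extents, sampled polygon moments, permutation tests) on 200+ random
fibers; render-vs-truth agreement within 2% of peak across seeds;
invariance to pixel size, rotation, joint channel scaling, and similarity
transforms; recovery of generator parameters (peak location quintile,
Poisson event rates at 100 tracks, crawl speed at 30 tracks); type-I
calibration of the *t*/ANOVA/dual rule on 10,000 simulated nulls; and a
20-replicate phenotype-ordering experiment at the full cohort design (4
muscles x 3 hemisegments x 10 embryos for positioning, 2 muscles for
profiles) in which the clumped-nuclei genotype must show greater
end-to-nucleus distance, reduced distal ratio with statistically
indistinguishable AUC, and a clean reference-channel control. These sizes
keep the whole suite within a few minutes on one CPU while leaving the
Monte-Carlo error well below every tolerance tested.

Two checks are worth flagging for what they are: the "not significant in
>= 95% of replicates" properties are Bernoulli checks on a ~5% false-positive
process observed 20 times, so a perfectly calibrated pipeline still has a
nontrivial chance of a borderline run; they are kept at those sizes
because they are the design the measurements come from.

## Limitations

Automatic segmentation is Otsu + connected components — a convenience for
clean, well-separated structures; hand-drawn masks are the reference
route, as they were for the original measurements. The pipeline analyzes
2-D projections only (a maximum-intensity projection operator is
provided); it does not track nuclei from raw movies (tracks are inputs or
simulated), does not assign muscle identities, and applies no background,
flat-field, or bleed-through correction.
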