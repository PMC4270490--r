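# Genotype presets for the synthetic fiber generator.
#
# Placement fractions are positions along the fiber long axis (0 = dorsal
# end, 1 = ventral end). Intensities are arbitrary units. The presets are
# calibrated to reproduce the ordering of phenotypes (end-enriched vs
# nucleus-enriched target signal; end-clustered vs centrally clumped
# nuclei), not absolute published values.

control:
  nucleus_placement: {cluster_centers: [0.10, 0.90], cluster_sd: 0.05, n_nuclei: 6}
  target_model: {baseline: 100, peak_amplitude: 150, peak_position: 0.0,
                 decay_length: 0.30, mixture_weight_diffuse: 0.10}
  reference_level: 200
  noise: {gaussian_sd: 6, poisson_like: true}

syd_like:
  nucleus_placement: {cluster_centers: [0.35, 0.65], cluster_sd: 0.06, n_nuclei: 6}
  target_model: {baseline: 100, peak_amplitude: 150, peak_position: 1.0,
                 decay_length: 0.30, mixture_weight_diffuse: 0.10}
  reference_level: 200
  noise: {gaussian_sd: 6, poisson_like: true}

khc_like:
  nucleus_placement: {cluster_centers: [0.30, 0.70], cluster_sd: 0.06, n_nuclei: 6}
  target_model: {baseline: 100, peak_amplitude: 150, peak_position: 1.0,
                 decay_length: 0.30, mixture_weight_diffuse: 0.10}
  reference_level: 200
  noise: {gaussian_sd: 6, poisson_like: true}

bsk_dn_like:
  nucleus_placement: {cluster_centers: [0.35, 0.65], cluster_sd: 0.07, n_nuclei: 6}
  target_model: {baseline: 100, peak_amplitude: 150, peak_position: 1.0,
                 decay_length: 0.30, mixture_weight_diffuse: 0.15}
  reference_level: 200
  noise: {gaussian_sd: 6, poisson_like: true}

hep_act_like:
  nucleus_placement: {cluster_centers: [0.20, 0.50, 0.80], cluster_sd: 0.08, n_nuclei: 6}
  target_model: {baseline: 100, peak_amplitude: 150, peak_position: 0.5,
                 decay_length: 0.30, mixture_weight_diffuse: 0.60}
  reference_level: 200
  noise: {gaussian_sd: 6, poisson_like: true}
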