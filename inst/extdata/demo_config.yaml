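seed: 42
out_dir: ailqtl_demo
stages:
  simulate: true
  qc: true
  scan: true
  causal: true
  de: true
  prioritize: true
simulate:
  n_individuals: 150
  n_generations: 9
  chromosomes:
    chr1: 100000000
    chr2: 100000000
  markers_per_chr: 60
  recombination_rate: 0.5
  n_select: 100
  qtl:
    - trait: gonat_weight
      marker_index: 30
      additive: -0.8
      noise: 1
    - trait: blood_glucose
      mediator: gonat_weight
      slope: -1.0
      noise: 0.5
  litter_traits: [liver_weight]
  litter_effect: 0
scan:
  simplem_window: 60
  simplem_C: 0.995
  alpha_significant: 0.05
  alpha_highly: 0.01
  lod_drop: 1.5
expression:
  n_probes: 300
  n_samples_per_line: 7
  de_fraction: 0.1
  effect_size_log2: 1
  noise_sd: 0.3
genes_per_chr: 40
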