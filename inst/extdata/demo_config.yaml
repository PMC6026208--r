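# Bundled synthetic demonstration study: every stage runs on generated data
# with known ground truth.  Override output_dir (and anything else) as needed.
output_dir: ommscreen_demo
master_seed: 2024
log_level: quiet
stages: [eyescore, epistasis, enrich, brainnet]
eyescore:
  n_images_per_level: 3
  jitter_levels: [0.0, 0.5, 1.5, 3.0]
  n_rows: 12
  n_cols: 12
  spacing: 10
  background_noise_sd: 0.02
epistasis:
  n_pairs_per_class: 3
  effect: 9
  within_sd: 2
  n_replicates: 10
  alpha: 0.05
enrich:
  n_genes: 4000
  n_models: 6
  n_de_per_model: 40
  shared_de_fraction: 0.4
  universe_size: 3000
  n_perm: 999
brainnet:
  n_nodes: 150
  edge_p: 0.05
  n_seeds: 8
  annotation_fraction: 0.15
  control_iterations: 20
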