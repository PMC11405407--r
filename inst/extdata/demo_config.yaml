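# Demonstration run: a small fully synthetic dataset exercising all six
# pipeline stages deterministically.
seed: 1
stages: [simulate, diff_ir, site_features, da, sg_score, cohort_dist]
simulation:
  n_genes: 30
  weak_fraction: 0.5
  depth: 200
  ir_effect: 0.3
  n_samples_per_group: 10
  n_cells: 300
  sg_fraction: 0.4
  noise_sd: 0.2
thresholds:
  fdr: 0.05
  dpsi: 0.02
  alpha: 0.05
  top_fraction: 0.05
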