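# Example run configuration for run_cohort() / inst/scripts/rdna-run.R
seed: 42
fdr_threshold: 0.05
alpha: 0.05
loss_region: 18S
simulate:
  projects: [proj1, proj2, proj3, proj4]
  n_pairs: [8, 8, 6, 6]
  positive_projects: [proj1, proj3]
  normal_cn_mean: 400
  normal_cn_sd: 50
  loss: 80
  n_exons: 2000
  n_gain_exons: 50
  depth: 30
  dispersion: 0.1
  unit_length: 4300
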