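# Demonstration pipeline configuration (desk scale).
synth:
  n: 300
  alpha: 0.3
  n_vertices: 600
  horizon: 10
  rate: 0.02
measurement:
  mode: constrained_density
  sigma: 1.5
  ectd_convention: point
  n_demo_vertices: 40
spm:
  method: permutation_fwer
  alpha: 0.05
  cluster_p: 0.001
  n_perm: 500
cv:
  folds: 5
models: [m, m+DXA, m+QCT, m+CBM]
precision:
  n_pairs: 19
  error_sd: {CTh: 0.1, CM: 9.0, CBMD: 35.0, ECTD: 15.0}
seeds:
  mesh: 1
  population: 2
  outcomes: 3
  case_cohort: 4
  repeat_scans: 5
  spm: 6
  boot: 7
  folds: 8
output: cbmfrax-demo-output
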