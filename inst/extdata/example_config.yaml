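# Example xtalmerge pipeline configuration.
# One 20-degree wedge per microcrystal; a minority of non-isomorphous
# outliers; default assembly settings (20 cell groups, 90% completeness
# gate, CC1/2 rejection objective).
seed: 1
simulate:
  n_crystals: 24
  cell0: {a: 25, b: 30, c: 35, alpha: 90, beta: 90, gamma: 90}
  sg: P212121
  d_min: 3.0
  wedge_width: 20
  frames_per_wedge: 10
  n_outliers: 4
  outlier_corr: 0.5
  outlier_cell_shift: 0.5
cluster:
  max_groups: 1
  reject_z: 6
merge:
  n_shells: 10
  n_splits: 8
reject:
  objective: cc_half
  tol: 0.001
  min_crystals: 3
  levels: [crystal]
  min_completeness: 0.90
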