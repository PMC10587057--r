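# Example run configuration for the gyrodesign command-line interface.
# A desk-scale campaign on 2 x 2 x 2 designs with a 3-level porosity ladder.
shape: 2
ladder: [0.3, 0.6, 0.9]
seed: 1
geometry:
  unit_size_mm: 2.0
  voxels_per_unit: 8
corpus:
  n_per_interval: 120
cae:
  epochs: 25
surrogate:
  epochs: 10
  lr: 0.002
  val_frac: 0
oracle:
  E0: 5000
  Y0: 120
constraints:
  E_target: 800
  E_band: 0.05
  mass_slack: 0.15
  epsilon: 0.05
stopping:
  margin: 0.10
  patience: 3
  max_rounds: 6
mall:
  n_samples: 2000
  k: 6
  n_initial: 60
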