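n_samples: 5.0
reads_per_sample: 50.0
depth_sdlog: 1.5
bacterial_only_per_sample: 20.0
class_read_shares:
  prophage: 0.92
  bacteriophage: 0.05
  eukaryotic_virus: 0.03
p_bacterial_homology:
  prophage: 0.945
  bacteriophage: 0.642
  eukaryotic_virus: 0.02
noise:
  identity_mean: 95.0
  identity_sd: 4.0
  coverage_shape1: 18.0
  coverage_shape2: 2.0
  fail_rate: 0.02
  off_target_rate: 0.02
seed: 21
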