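# Demo configuration: small synthetic study exercising the whole pipeline.
seed: 7
simulate:
  n_major: 2
  leafs_per_major: 2
  n_classes: 3
  class_effect: 2
  smoothness_scale: 10
  n_per_cell: 3
  noise_sd: 0.2
estimator:
  kind: el
  sigma_x: [200, 1600]
  sigma_c: [0.05, 1]
  alpha: [0, 0.5, 1]
nmf:
  enabled: true
  q: 3
  replicates: 4
  mask_threshold_um: 150
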