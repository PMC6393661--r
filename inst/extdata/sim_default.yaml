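# Study-design configuration: 3 case vs 3 control samples, as in the
# embryonic palate profiling design the simulator emulates.
sim:
  n_case: 3
  n_control: 3
  n_mrna: 500
  n_lncrna: 50
  n_tf: 10
  regulon_size: 20
  n_planted_triads: 5
  de_log2fc: 1.5
  activity_weight: 1.0
  noise_sd: 0.3
  seed: 1
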