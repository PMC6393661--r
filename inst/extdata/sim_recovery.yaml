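# Parameter-recovery configuration: larger groups (10 vs 10) because Pearson
# correlation at n = 6 is too variable for stable recovery statements.
# Triad targets are not intersected with the DE list here: recovery measures
# the co-expression + regulon-overlap machinery.
sim:
  n_case: 10
  n_control: 10
  n_mrna: 500
  n_lncrna: 50
  n_tf: 10
  regulon_size: 20
  n_planted_triads: 5
  de_log2fc: 1.5
  activity_weight: 1.0
  noise_sd: 0.3
  seed: 1
de_filter_targets: false
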