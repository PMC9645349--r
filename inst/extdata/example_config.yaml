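# Example pipeline configuration: a half-size survey with the default
# marginals and per-arm coefficient truths.
seed: 20260920
population:
  n_respondents: 1000
  arm_split: 0.4988
valuation:
  victim_reference_loss: 537000000
  baseline_annual_risk: 0.000005
  reduction_rate: 0.5
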