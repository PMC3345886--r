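# Demo pipeline configuration: simulate a two-region edge-of-range
# landscape, fit a model by forward stepwise selection in the training
# region, transfer it to the target region, evaluate both, write maps.
seed: 20260920
scenario:
  n_rows: 50
  n_cols: 50
  shift: true
fit:
  candidates: [Alti, Prec, SRad, DPre, Lati]
  entry_alpha: 0.05
threshold_policy: default
prevalence_source: training
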