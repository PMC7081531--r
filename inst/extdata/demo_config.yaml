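# Demo simulation config for the triocall CLI (triocall.R simulate/pipeline)
simulate:
  n_markers: 500
  n_mothers: 5
  n_fathers: 5
  offspring_per_cross: 6
  offspring_ploidy: 3
  genotype_error_rate: 0.005
  crossover_rate: 1.0
  seed: 1
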