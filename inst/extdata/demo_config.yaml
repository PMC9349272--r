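# Demo pipeline configuration: a small cohort that runs end-to-end on one
# CPU in well under five minutes.
seed: 42
cohort:
  n_samples: 150
  n_snps: 600
  n_blocks: 60
  n_probes: 4000
  n_coupled_probes: 40
  coupling_effect: 0.4
ewas:
  bacon_iterations: 5000
  bacon_burnin: 2000
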