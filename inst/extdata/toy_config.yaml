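# Toy pipeline configuration: a small dataset that runs end to end in a few
# minutes on one CPU. All thresholds shown are the package defaults.
simulation:
  n_tissues: 5
  n_genes: 60
  frac_tra: 0.3
  frac_aire: 0.4
  tec_isoform_fraction: 0.5
  planted_delta_psi: 0.4
  event_coverage: 100
  seed: 1
motifs:
  n_perm: 200
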