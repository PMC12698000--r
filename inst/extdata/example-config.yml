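# Example experiment configuration: overrides are merged onto the package
# defaults and re-validated; all other parameters keep their calibrated
# defaults (see dump_defaults() for the full set with provenance tags).
seed: 7
input:
  trial_duration: 20
  burst_fraction: 0.0
neuron:
  variant: spike_trace
  m_csd: 0
plasticity:
  eta: 0.5
selectivity:
  threshold_scale: sem
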