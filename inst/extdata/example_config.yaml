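# Example scenario configuration for ttcasim.
# Select a preset and override any of its fields; the mesh block feeds
# the synthetic geometry generator.
preset: fig4_heterogeneous
dt: 0.5
output_every: 5
mesh:
  variant: branched
  seed: 42
  target_edge_length: 0.09
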