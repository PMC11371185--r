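# Example run configuration for the pipeline.
n_cells: 29
seed: 20
gof_policy: both
reference: AACC_wt
count_univalents_as_zero: true
output_dir: meioscope_out
presets:
  aaCc:
    nu: 1.0
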