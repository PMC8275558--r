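{
  "n_subjects": 1200,
  "seed": 7,
  "out_dir": "gdikit_out",
  "adjustment": "model1",
  "alpha_screen": 0.05,
  "alpha_family": 0.05,
  "missing_rate": 0.005
}
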