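{
  "label": "symmetric-1d",
  "mass": 12,
  "domain": [-0.6, 1.6],
  "diabat1": {"form": "harmonic", "k": 300, "x0": 0.0, "offset": 0.0},
  "diabat2": {"form": "harmonic", "k": 300, "x0": 1.0, "offset": 0.0},
  "coupling": {"delta_alpha": 0.0, "H12": 5.0},
  "targets": {"dG0": 0.0}
}
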