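{
  "label": "reference-1d",
  "mass": 12,
  "domain": [-0.6, 1.6],
  "diabat1": {"form": "harmonic", "k": 300, "x0": 0.0, "offset": 0.0},
  "diabat2": {"form": "harmonic", "k": 300, "x0": 1.0, "offset": 0.0},
  "coupling": {"delta_alpha": -13.5, "H12": 7.5},
  "targets": {"dG_act": 24.5, "dG0": -12.8, "temperature": 298}
}
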