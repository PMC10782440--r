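{
  "label": "toy-reference",
  "spec": {
    "n_solvent": 20,
    "restraint_radius": 8,
    "restraint_k": 10,
    "catalyst": false
  },
  "coupling": {"delta_alpha": -10.0, "H12": 3.0}
}
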