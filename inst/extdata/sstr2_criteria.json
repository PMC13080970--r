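{
  "distance": {
    "residues": [218, 306],
    "threshold_angstrom": 19.0,
    "active_when": "below"
  },
  "angle": {
    "residues": [262, 269, 81],
    "threshold_degrees": 45.0,
    "active_when": "above"
  },
  "atom_name": "CA",
  "combine": "and"
}
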