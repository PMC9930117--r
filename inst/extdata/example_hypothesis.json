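{
  "name": "example-acid-aromatic",
  "features": [
    {"kind": "N", "x": 0.0, "y": 0.0, "z": 0.0, "tolerance": 1.6},
    {"kind": "A", "x": 3.2, "y": 0.4, "z": 0.8, "tolerance": 1.6},
    {"kind": "R", "x": -3.4, "y": 1.1, "z": -0.5, "tolerance": 1.6},
    {"kind": "R", "x": -6.9, "y": 0.2, "z": 0.3, "tolerance": 1.6}
  ]
}
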