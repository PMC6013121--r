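{
  "fkr": ["A1", "A4", "B1", "B2"],
  "hub_count": 10,
  "min_levels": 2,
  "level1_modules": {
    "A": ["A1", "A2", "A3", "A4", "A5", "A6"],
    "B": ["B1", "B2", "B3", "B4", "B5", "B6"],
    "C": ["C1", "C2", "C3", "C4", "C5"],
    "D": ["D1", "D2", "D3", "D4", "D5"]
  }
}
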