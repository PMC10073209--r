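{
  "topology": "figure8",
  "inner_diameter_mm": 42,
  "outer_diameter_mm": 70,
  "turns": 9,
  "wire_width_mm": 1.5,
  "wire_height_mm": 2,
  "turn_gap_mm": 0.05,
  "current_A": 5000,
  "voltage_V": 2000,
  "frequency_Hz": 20,
  "label": "synthetic human figure-8 coil (70 mm lobes)"
}
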