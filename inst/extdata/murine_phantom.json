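{
  "layers": [
    {"tissue": "scalp",     "thickness_um": 500,  "permittivity": 3056, "conductivity_S_per_m": 0.0009},
    {"tissue": "skull",     "thickness_um": 1000, "permittivity": 1246, "conductivity_S_per_m": 0.0203},
    {"tissue": "dura",      "thickness_um": 300,  "permittivity": 2360, "conductivity_S_per_m": 0.5010},
    {"tissue": "arachnoid", "thickness_um": 75,   "permittivity": 3013, "conductivity_S_per_m": 0.0650},
    {"tissue": "brain",     "thickness_um": 890,  "permittivity": 6683, "conductivity_S_per_m": 0.1056}
  ],
  "standoff_mm": 0
}
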