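[
  {
    "name": "RTVue XR Avanti",
    "p_factor": 3.48,
    "reference_al_mm": 23.95,
    "scan_width_mm": 3
  }
]
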